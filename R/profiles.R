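# Sequence profiles: per-position frequency (PSFM) and log-odds score
# (PSSM) matrices over the 20 standard residues, either parsed from
# PSI-BLAST ASCII output or derived from the sequence alone.

new_profile <- function(freq, score, source) {
  stopifnot(is.matrix(freq), is.matrix(score),
            ncol(freq) == 20L, ncol(score) == 20L,
            nrow(freq) == nrow(score))
  colnames(freq) <- AA20
  colnames(score) <- AA20
  structure(list(freq = freq, score = score, source = source),
            class = "peptide_profile")
}

#' @export
print.peptide_profile <- function(x, ...) {
  cat(sprintf("<peptide_profile> %d positions, source '%s'\n",
              nrow(x$freq), x$source))
  invisible(x)
}

profile_length <- function(profile) nrow(profile$freq)

#' Derive a pseudo-profile from a bare sequence
#'
#' When PSI-BLAST profiles are unavailable, each position gets a frequency
#' row that mixes a point mass on the observed residue with the background
#' distribution, `(1 - lambda) * delta + lambda * background`, and a score
#' row equal to the BLOSUM62 row of the observed residue. Padding (`X`)
#' positions get the pure background distribution and all-zero scores. The
#' construction is deterministic.
#'
#' @param sequence Residue string (may contain `X`).
#' @param lambda Background mixing coefficient, default 0.3.
#' @return A `peptide_profile` with one row per residue of `sequence`.
#' @export
pseudo_profile <- function(sequence, lambda = 0.3) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0) {
    abort("sequence must be a non-empty string", class = "phoskin_input_error")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), AA21)
  if (length(bad) > 0) {
    abort(paste0("unknown residue(s): ", paste(bad, collapse = ", ")),
          class = "phoskin_input_error")
  }
  n <- length(chars)
  bg <- BLOSUM62_BACKGROUND
  freq <- matrix(rep(bg, each = n), nrow = n, ncol = 20L,
                 dimnames = list(NULL, AA20))
  score <- matrix(0, nrow = n, ncol = 20L, dimnames = list(NULL, AA20))
  m <- blosum62()
  std <- chars != "X"
  if (any(std)) {
    freq[std, ] <- lambda * freq[std, , drop = FALSE]
    freq[cbind(which(std), match(chars[std], AA20))] <-
      freq[cbind(which(std), match(chars[std], AA20))] + (1 - lambda)
    score[std, ] <- m[chars[std], AA20, drop = FALSE]
  }
  new_profile(freq, score, "pseudo")
}

#' Parse a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Reads the text PSSM emitted by `blastpgp -Q` / `psiblast
#' -out_ascii_pssm`: one row per residue of the query with 20 integer
#' log-odds columns followed by 20 percentage (weighted observed frequency)
#' columns. Frequencies are renormalised to sum to one per row; rows whose
#' percentages are all zero (no observed alignment weight) fall back to the
#' background distribution.
#'
#' @param path Path to the ASCII PSSM file.
#' @param sequence Optional protein sequence to validate row count and
#'   residues against.
#' @return A `peptide_profile` of length equal to the protein.
#' @export
read_pssm <- function(path, sequence = NULL) {
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "\\s+")
  is_row <- vapply(toks, function(t) {
    length(t) >= 42L && grepl("^[0-9]+$", t[1L]) && t[2L] %in% AA21
  }, logical(1))
  rows <- toks[is_row]
  if (length(rows) == 0) {
    abort(paste0("no PSSM rows found in ", path),
          class = "phoskin_format_error")
  }
  n <- length(rows)
  score <- matrix(0, n, 20L, dimnames = list(NULL, AA20))
  freq <- matrix(0, n, 20L, dimnames = list(NULL, AA20))
  residues <- character(n)
  for (r in seq_len(n)) {
    t <- rows[[r]]
    residues[r] <- t[2L]
    vals <- suppressWarnings(as.numeric(t[3:42]))
    if (anyNA(vals)) {
      abort(sprintf("non-numeric PSSM cell at data row %d of %s", r, path),
            class = "phoskin_format_error")
    }
    score[r, ] <- vals[1:20]
    pct <- vals[21:40]
    if (sum(pct) <= 0) {
      freq[r, ] <- BLOSUM62_BACKGROUND
    } else {
      freq[r, ] <- pct / sum(pct)
    }
  }
  if (!is.null(sequence)) {
    if (nchar(sequence) != n) {
      abort(sprintf("PSSM has %d rows but sequence has %d residues (%s)",
                    n, nchar(sequence), path),
            class = "phoskin_format_error")
    }
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    if (!all(residues == chars | chars == "X")) {
      abort(paste0("PSSM residue column disagrees with the sequence: ", path),
            class = "phoskin_format_error")
    }
  }
  new_profile(freq, score, "psiblast")
}

#' Slice a whole-protein profile to a peptide window
#'
#' Rows outside the protein (terminal padding) get the background frequency
#' distribution and all-zero scores, mirroring the `X` convention of
#' [extract_window()].
#'
#' @param profile A `peptide_profile` covering the whole protein.
#' @param pos 1-based centre position.
#' @param half_width Rows taken on each side of the centre.
#' @return A `peptide_profile` of length `2 * half_width + 1`.
#' @export
profile_window <- function(profile, pos, half_width = 20L) {
  n <- profile_length(profile)
  if (pos < 1L || pos > n) {
    abort(sprintf("position %d outside profile of length %d", pos, n),
          class = "phoskin_input_error")
  }
  idx <- seq.int(pos - half_width, pos + half_width)
  L <- length(idx)
  freq <- matrix(rep(BLOSUM62_BACKGROUND, each = L), L, 20L,
                 dimnames = list(NULL, AA20))
  score <- matrix(0, L, 20L, dimnames = list(NULL, AA20))
  ok <- idx >= 1L & idx <= n
  freq[ok, ] <- profile$freq[idx[ok], , drop = FALSE]
  score[ok, ] <- profile$score[idx[ok], , drop = FALSE]
  new_profile(freq, score, profile$source)
}

#' Write / read a single peptide profile as TSV
#'
#' On-disk layout: one row per window position with columns `residue`,
#' `f_<AA>` (20 frequencies) and `s_<AA>` (20 scores); tab-separated,
#' plain text.
#'
#' @param profile A `peptide_profile`.
#' @param residues Residue string of the window (stored for readability).
#' @param path Output/input file path.
#' @return `write_profile` returns `path` invisibly; `read_profile` returns
#'   a `peptide_profile`.
#' @export
write_profile <- function(profile, residues, path) {
  df <- data.frame(residue = strsplit(residues, "", fixed = TRUE)[[1L]],
                   profile$freq, profile$score, check.names = FALSE)
  names(df) <- c("residue", paste0("f_", AA20), paste0("s_", AA20))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @param source Source tag to record on the re-read profile.
#' @export
read_profile <- function(path, source = "psiblast") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  freq <- as.matrix(df[paste0("f_", AA20)])
  score <- as.matrix(df[paste0("s_", AA20)])
  prof <- new_profile(unname(freq), unname(score), source)
  attr(prof, "residues") <- paste(df$residue, collapse = "")
  prof
}
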