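# Residue alphabet, substitution matrix, window extraction and the
# parameter rules shared by every other module.

# PSI-BLAST column order; also the column order of every profile matrix.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA21 <- c(AA20, "X")

PHOSPHO_RESIDUES <- c("S", "T", "Y")

# BLOSUM62 marginal (background) amino-acid frequencies, AA20 order.
BLOSUM62_BACKGROUND <- c(
  A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025,
  Q = 0.034, E = 0.054, G = 0.074, H = 0.026, I = 0.068,
  L = 0.099, K = 0.058, M = 0.025, F = 0.047, P = 0.039,
  S = 0.057, T = 0.051, W = 0.013, Y = 0.032, V = 0.073
)
BLOSUM62_BACKGROUND <- BLOSUM62_BACKGROUND / sum(BLOSUM62_BACKGROUND)

.phoskin_env <- new.env(parent = emptyenv())

#' Amino-acid alphabet used throughout the package
#'
#' @param padding If `TRUE` (default) include the padding/unknown symbol `X`.
#' @return Character vector of one-letter residue codes in PSI-BLAST column
#'   order.
#' @export
aa_alphabet <- function(padding = TRUE) {
  if (padding) AA21 else AA20
}

#' Background amino-acid distribution
#'
#' The marginal amino-acid frequencies underlying BLOSUM62, normalised to
#' sum to one. Used for padding positions of profiles, for pseudo-profiles
#' and as the residue distribution of synthetic background sequence.
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
background_frequencies <- function() {
  BLOSUM62_BACKGROUND
}

#' The BLOSUM62 substitution matrix (with the X row)
#'
#' Returns the 21 x 21 integer substitution matrix over the 20 standard
#' residues plus `X` (unknown / terminal padding), in the NCBI dialect in
#' which `X` scores -1 against most residues. Taken from the matrix shipped
#' with Biostrings.
#'
#' @return Symmetric integer matrix with dimnames over `aa_alphabet()`.
#' @export
blosum62 <- function() {
  if (is.null(.phoskin_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62[AA21, AA21]
    storage.mode(m) <- "double"
    .phoskin_env$blosum62 <- m
  }
  .phoskin_env$blosum62
}

#' Extract a fixed window around a sequence position
#'
#' Returns the `2 * half_width + 1` residues centred on `pos`, padding
#' positions that fall outside the sequence with `X`. This is how peptide
#' windows near the N or C terminus are represented.
#'
#' @param sequence Protein sequence (single string, upper case).
#' @param pos 1-based position of the centre residue.
#' @param half_width Number of residues taken on each side of the centre.
#' @param protein_id Optional id used in error messages.
#' @return String of length `2 * half_width + 1`.
#' @examples
#' extract_window("MKRSAT", 4, 3)  # "MKRSATX"
#' extract_window("S", 1, 3)      # "XXXSXXX"
#' @export
extract_window <- function(sequence, pos, half_width, protein_id = "?") {
  stopifnot(is.character(sequence), length(sequence) == 1L, half_width >= 0)
  n <- nchar(sequence)
  if (is.na(pos) || pos < 1L || pos > n) {
    abort(sprintf("position %s is outside protein '%s' (length %d)",
                  as.character(pos), protein_id, n),
          class = "phoskin_input_error")
  }
  idx <- seq.int(pos - half_width, pos + half_width)
  chars <- rep("X", length(idx))
  ok <- idx >= 1L & idx <= n
  chars[ok] <- strsplit(sequence, "", fixed = TRUE)[[1L]][idx[ok]]
  paste(chars, collapse = "")
}

#' Build peptide windows for a table of candidate sites
#'
#' Adds the 7-residue and 41-residue windows (and a peptide id) to a table
#' of sites. The 7-window is the central slice of the 41-window; both are
#' X-padded at the termini.
#'
#' @param sites Data frame with columns `protein_id`, `position`, `residue`.
#' @param sequences Named character vector of protein sequences.
#' @return `sites` as a tibble with added columns `id`, `window7`,
#'   `window41`.
#' @export
peptide_windows <- function(sites, sequences) {
  stopifnot(all(c("protein_id", "position", "residue") %in% names(sites)))
  sites <- as_tibble(sites)
  missing <- setdiff(unique(sites$protein_id), names(sequences))
  if (length(missing) > 0) {
    abort(paste0("proteins absent from the sequence set: ",
                 paste(missing, collapse = ", ")),
          class = "phoskin_input_error")
  }
  w41 <- purrr::map2_chr(sites$protein_id, sites$position, function(p, i) {
    extract_window(sequences[[p]], i, 20L, protein_id = p)
  })
  w7 <- substr(w41, 18L, 24L)
  centre <- substr(w7, 4L, 4L)
  if (!all(centre == sites$residue)) {
    bad <- which(centre != sites$residue)[1L]
    abort(sprintf(
      "residue mismatch for %s position %d: table says %s, sequence has %s",
      sites$protein_id[bad], sites$position[bad],
      sites$residue[bad], centre[bad]), class = "phoskin_input_error")
  }
  dplyr::mutate(sites,
                id = paste0(.data$protein_id, "_", .data$position),
                window7 = w7, window41 = w41,
                .after = "residue")
}

#' Noise-reduction parameters
#'
#' Container for the four parameters of the indirect-relationship noise
#' reducer: `alpha` (number of top direct hits retrieved for the query and
#' for every hit when the indirect matrix is built), `beta` (number of top
#' peptides by indirect score whose labels are inspected), `gamma` (the
#' decision threshold: the query is called positive when strictly more than
#' `gamma` of the top `beta` are positives) and `weight` (the factor applied
#' to relationships whose partner peptide is a positive, compensating for
#' the negative:positive imbalance of the reference set).
#'
#' @param alpha,beta,gamma,weight See description.
#' @return Object of class `noise_params`.
#' @export
noise_params <- function(alpha, beta, gamma, weight) {
  stopifnot(alpha >= 1, beta >= 1, gamma >= 0, weight > 0)
  if (gamma >= beta) {
    abort("gamma must be smaller than beta", class = "phoskin_input_error")
  }
  structure(list(alpha = as.integer(alpha), beta = as.integer(beta),
                 gamma = as.integer(gamma), weight = as.numeric(weight)),
            class = "noise_params")
}

#' @export
print.noise_params <- function(x, ...) {
  cat(sprintf("<noise_params> alpha=%d beta=%d gamma=%d weight=%g\n",
              x$alpha, x$beta, x$gamma, x$weight))
  invisible(x)
}

#' Default noise-reduction parameters from reference-set size
#'
#' Applies the published parameter rules: `alpha` is half the number of
#' positive peptides, `beta` one third and `gamma` one quarter (floors, with
#' a minimum of 1 for `alpha` and `beta`; `gamma` may be 0 and is reduced to
#' `beta - 1` if the floors would violate `gamma < beta`). The positive
#' weight defaults to the realised negative:positive ratio, which equals 10
#' under the standard 10:1 sampling; `force_weight` overrides it.
#'
#' @param n_positive,n_negative Counts of labelled reference peptides.
#' @param force_weight Optional fixed positive weight (e.g. `10`).
#' @return Object of class [noise_params()].
#' @examples
#' default_noise_params(84, 840)  # alpha 42, beta 28, gamma 21, weight 10
#' @export
default_noise_params <- function(n_positive, n_negative, force_weight = NULL) {
  if (n_positive < 1 || n_negative < 1) {
    abort("reference set must contain at least one peptide of each label",
          class = "phoskin_input_error")
  }
  alpha <- max(1L, n_positive %/% 2L)
  beta <- max(1L, n_positive %/% 3L)
  gamma <- n_positive %/% 4L
  if (gamma >= beta) gamma <- beta - 1L
  weight <- if (is.null(force_weight)) n_negative / n_positive else force_weight
  noise_params(alpha, beta, gamma, weight)
}
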