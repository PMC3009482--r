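# The three peptide similarity scores: windowed BLOSUM62 similarity,
# gapped profile-profile alignment, and their product.

#' Alignment parameters for the profile-profile score
#'
#' @param gap_open Cost of the first column of a gap (default 3.0).
#' @param gap_extend Cost of each further column (default 0.75). A gap of
#'   length L costs `gap_open + (L - 1) * gap_extend`; end gaps are
#'   penalised in global mode.
#' @param mode `"global"` (default; both 41-windows aligned end to end) or
#'   `"local"` for sensitivity analyses.
#' @param window Profile window length (default 41).
#' @return Object of class `align_params`.
#' @export
align_params <- function(gap_open = 3.0, gap_extend = 0.75,
                         mode = c("global", "local"), window = 41L) {
  mode <- match.arg(mode)
  stopifnot(gap_open >= gap_extend, gap_extend > 0, window >= 1)
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 mode = mode, window = as.integer(window)),
            class = "align_params")
}

pep7_codes <- function(window7) {
  stopifnot(all(nchar(window7) == 7L))
  codes <- matrix(match(unlist(strsplit(window7, "", fixed = TRUE)), AA21) - 1L,
                  ncol = 7L, byrow = TRUE)
  if (anyNA(codes)) {
    abort("peptide window contains a residue outside the alphabet",
          class = "phoskin_input_error")
  }
  codes
}

#' Windowed BLOSUM62 peptide similarity
#'
#' Sum of the substitution-matrix scores of the seven aligned residue pairs
#' of two 7-windows centred on the candidate sites; symmetric in its
#' arguments. `X` (terminal padding) uses the matrix's own X row.
#'
#' @param window7_a,window7_b 7-residue windows.
#' @param matrix Substitution matrix, default [blosum62()].
#' @param zero_x If `TRUE`, residue pairs involving the padding symbol `X`
#'   contribute 0 instead of the matrix's X scores.
#' @return A single numeric score.
#' @examples
#' s_blosum62("AAAAAAA", "AAAAAAA")  # 7 * 4 = 28
#' @export
s_blosum62 <- function(window7_a, window7_b, matrix = blosum62(),
                       zero_x = FALSE) {
  if (nchar(window7_a) != 7L || nchar(window7_b) != 7L) {
    abort("s_blosum62 requires 7-residue windows",
          class = "phoskin_input_error")
  }
  a <- strsplit(window7_a, "", fixed = TRUE)[[1L]]
  b <- strsplit(window7_b, "", fixed = TRUE)[[1L]]
  v <- matrix[cbind(a, b)]
  if (zero_x) v[a == "X" | b == "X"] <- 0
  sum(v)
}

#' Profile-profile column score
#'
#' Scores the pairing of position `i` of profile `a` with position `j` of
#' profile `b` by cross-multiplying each profile's observed frequencies
#' with the other's log-odds scores:
#' `0.5 * sum_k (f_ik * S_jk + f_jk * S_ik)`. Symmetric in (a, i) vs (b, j).
#'
#' @param prof_a,prof_b `peptide_profile` objects.
#' @param i,j 1-based positions in `prof_a` and `prof_b`.
#' @return A single numeric score.
#' @export
ppa_score <- function(prof_a, i, prof_b, j) {
  if (i < 1L || i > profile_length(prof_a) ||
      j < 1L || j > profile_length(prof_b)) {
    abort("profile position out of range", class = "phoskin_input_error")
  }
  0.5 * (sum(prof_a$freq[i, ] * prof_b$score[j, ]) +
         sum(prof_b$freq[j, ] * prof_a$score[i, ]))
}

#' Gapped profile-profile alignment score
#'
#' Optimal affine-gap alignment of two profile windows, with
#' [ppa_score()] as the column-pair substitution score. The default is a
#' global alignment of two 41-windows with gap open 3.0 and extension 0.75.
#' Deterministic and symmetric.
#'
#' @param prof_a,prof_b `peptide_profile` objects of length
#'   `params$window`.
#' @param params An [align_params()] object.
#' @return A single numeric score.
#' @export
s_profile <- function(prof_a, prof_b, params = align_params()) {
  if (profile_length(prof_a) != params$window ||
      profile_length(prof_b) != params$window) {
    abort(sprintf("profiles must have length %d", params$window),
          class = "phoskin_input_error")
  }
  S <- ppa_matrix_cpp(prof_a$freq, prof_a$score, prof_b$freq, prof_b$score)
  affine_align_cpp(S, params$gap_open, params$gap_extend,
                   params$mode == "local")
}

#' Combined peptide similarity
#'
#' The product of the BLOSUM62 window score and the profile alignment
#' score when both are positive; 0 otherwise (so that two dissimilarities
#' cannot multiply into a similarity). All components are returned for
#' diagnostics, including the unclamped raw product.
#'
#' @param window7_a,window7_b 7-residue windows.
#' @param prof_a,prof_b 41-window `peptide_profile`s.
#' @param matrix Substitution matrix.
#' @param params An [align_params()] object.
#' @return One-row tibble with columns `s_blosum`, `s_profile`,
#'   `s_combined`, `raw_product`.
#' @export
s_combined <- function(window7_a, window7_b, prof_a, prof_b,
                       matrix = blosum62(), params = align_params()) {
  sb <- s_blosum62(window7_a, window7_b, matrix)
  sp <- s_profile(prof_a, prof_b, params)
  tibble(s_blosum = sb, s_profile = sp,
         s_combined = if (sb > 0 && sp > 0) sb * sp else 0,
         raw_product = sb * sp)
}

#' All-pairs similarity matrices for a reference set
#'
#' Computes the symmetric `s_blosum`, `s_profile` and `s_combined` matrices
#' over every peptide pair of a reference set (diagonal = self scores,
#' flagged by the object's `ids`). This is the precomputation consumed by
#' the noise-reducing classifier and the cross-validation harness.
#'
#' @param ref A `ref_set` (or any list with `peptides` and `profiles` in
#'   the same shape).
#' @param params An [align_params()] object.
#' @param matrix Substitution matrix.
#' @param cache Optional path to a TSV cache; if it exists it is read
#'   instead of recomputing, otherwise the computed pairs are written there.
#' @return Object of class `similarity_matrix` with elements `s_blosum`,
#'   `s_profile`, `s_combined` (named matrices), `ids` and `labels`.
#' @export
similarity_matrix <- function(ref, params = align_params(),
                              matrix = blosum62(), cache = NULL) {
  ids <- ref$peptides$id
  labels <- ref_labels(ref)
  if (!is.null(cache) && file.exists(cache)) {
    return(read_similarity_cache(cache, ids, labels))
  }
  if (length(ids) == 0) {
    empty <- array(numeric(0), dim = c(0L, 0L))
    return(new_similarity_matrix(empty, empty, empty, ids, labels))
  }
  profs <- ref$profiles[ids]
  res <- pairwise_scores_cpp(purrr::map(profs, "freq"),
                             purrr::map(profs, "score"),
                             pep7_codes(ref$peptides$window7),
                             matrix, params$gap_open, params$gap_extend,
                             params$mode == "local")
  out <- new_similarity_matrix(res$s_blosum, res$s_profile, res$s_combined,
                               ids, labels)
  if (!is.null(cache)) write_similarity_cache(out, cache)
  out
}

new_similarity_matrix <- function(sb, sp, sc, ids, labels) {
  dimnames(sb) <- dimnames(sp) <- dimnames(sc) <- list(ids, ids)
  structure(list(s_blosum = sb, s_profile = sp, s_combined = sc,
                 ids = ids, labels = labels),
            class = "similarity_matrix")
}

#' Wrap a precomputed score table as a similarity object
#'
#' Injection hook for the noise-reduction machinery: accepts an explicit
#' symmetric `s_combined` matrix (e.g. hand-constructed worked examples)
#' in place of live similarity computation.
#'
#' @param s_combined Symmetric numeric matrix with peptide ids as dimnames.
#' @param labels Named character vector (`"positive"` / `"negative"`) for
#'   the reference peptides (queries may be unlabeled).
#' @param s_blosum,s_profile Optional component matrices (default
#'   `s_combined`, so direct-feature classification falls back to the
#'   injected scores).
#' @return A `similarity_matrix`.
#' @export
injected_similarity <- function(s_combined, labels,
                                s_blosum = s_combined,
                                s_profile = s_combined) {
  stopifnot(is.matrix(s_combined), nrow(s_combined) == ncol(s_combined),
            !is.null(rownames(s_combined)))
  new_similarity_matrix(s_blosum, s_profile, s_combined,
                        rownames(s_combined), labels)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d peptides\n", length(x$ids)))
  invisible(x)
}

#' @method tidy similarity_matrix
#' @export
tidy.similarity_matrix <- function(x, ...) {
  n <- length(x$ids)
  if (n == 0) {
    return(tibble(id_i = character(), id_j = character(),
                  s_blosum = numeric(), s_profile = numeric(),
                  s_combined = numeric()))
  }
  pairs <- which(upper.tri(x$s_combined, diag = FALSE), arr.ind = TRUE)
  tibble(id_i = x$ids[pairs[, 1L]], id_j = x$ids[pairs[, 2L]],
         s_blosum = x$s_blosum[pairs], s_profile = x$s_profile[pairs],
         s_combined = x$s_combined[pairs])
}

write_similarity_cache <- function(sim, path) {
  readr::write_tsv(tidy(sim), path, progress = FALSE)
  invisible(path)
}

read_similarity_cache <- function(path, ids, labels) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  n <- length(ids)
  sb <- sp <- sc <- matrix(0, n, n, dimnames = list(ids, ids))
  ii <- cbind(match(df$id_i, ids), match(df$id_j, ids))
  if (anyNA(ii)) {
    abort("similarity cache does not match the reference set",
          class = "phoskin_format_error")
  }
  fill <- function(m, v) {
    m[ii] <- v
    m[ii[, c(2L, 1L), drop = FALSE]] <- v
    m
  }
  sb <- fill(sb, df$s_blosum)
  sp <- fill(sp, df$s_profile)
  sc <- fill(sc, df$s_combined)
  # diagonals are self scores; recompute cheaply is not possible here, so
  # cached objects carry zero diagonals, which no consumer reads (the
  # query itself is always excluded from rankings).
  new_similarity_matrix(sb, sp, sc, ids, labels)
}
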