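# Scanning query proteins for candidate phosphorylation sites and scoring
# every candidate against a reference set.

#' Predict phosphorylation sites in query proteins
#'
#' Scans each query protein for candidate residues (every residue type that
#' occurs as a positive centre in the reference set, e.g. S and T for a
#' serine/threonine kinase group), scores each candidate against the
#' reference with the noise-reducing classifier, and reports a confidence
#' (the fraction of positive peptides among the top `beta` indirect hits).
#' A site is called phosphorylated when its confidence reaches
#' `threshold` (>= comparison; default 0.5).
#'
#' @param ref A `ref_set`.
#' @param sequences Named character vector of query protein sequences.
#' @param threshold Confidence threshold for the final call (default 0.5).
#' @param params Optional fixed [noise_params()]; default: the published
#'   rules applied to the reference counts.
#' @param align An [align_params()] object.
#' @param profiles Optional named list of whole-protein `peptide_profile`s
#'   for the queries; pseudo-profiles are derived otherwise.
#' @param sim Optional precomputed [similarity_matrix()] of `ref`.
#' @return Tibble with one row per candidate site: `protein_id`,
#'   `position`, `residue`, `kinase`, `confidence`, `predicted` (logical),
#'   `n_pos_top_beta`, `beta`, `gamma`.
#' @export
predict_sites <- function(ref, sequences, threshold = 0.5, params = NULL,
                          align = align_params(), profiles = NULL,
                          sim = NULL) {
  counts <- ref_counts(ref)
  if (is.null(params)) {
    params <- default_noise_params(counts[["n_positive"]],
                                   counts[["n_negative"]],
                                   force_weight = ref$force_weight)
  }
  types <- sort(unique(ref$peptides$residue[ref$peptides$label == "positive"]))
  cand <- purrr::map_dfr(names(sequences), function(p) {
    chars <- strsplit(sequences[[p]], "", fixed = TRUE)[[1L]]
    hit <- which(chars %in% types)
    tibble(protein_id = p, position = hit, residue = chars[hit])
  })
  if (nrow(cand) == 0) {
    warn("no candidate residues found in the query sequences")
    return(tibble(protein_id = character(), position = integer(),
                  residue = character(), kinase = character(),
                  confidence = numeric(), predicted = logical(),
                  n_pos_top_beta = integer(), beta = integer(),
                  gamma = integer()))
  }
  cand <- peptide_windows(cand, sequences)
  # Query ids must not collide with reference ids.
  cand$qid <- paste0("query_", cand$id)
  qprofs <- purrr::map(seq_len(nrow(cand)), function(i) {
    p <- cand$protein_id[i]
    if (!is.null(profiles) && p %in% names(profiles)) {
      profile_window(profiles[[p]], cand$position[i], 20L)
    } else {
      pseudo_profile(cand$window41[i])
    }
  })

  if (is.null(sim)) sim <- similarity_matrix(ref, params = align)
  rprofs <- ref$profiles[sim$ids]
  qr <- query_scores_cpp(purrr::map(qprofs, "freq"),
                         purrr::map(qprofs, "score"),
                         pep7_codes(cand$window7),
                         purrr::map(rprofs, "freq"),
                         purrr::map(rprofs, "score"),
                         pep7_codes(ref$peptides$window7[match(sim$ids, ref$peptides$id)]),
                         blosum62(), align$gap_open, align$gap_extend,
                         align$mode == "local")

  res <- purrr::map_dfr(seq_len(nrow(cand)), function(i) {
    ids <- c(sim$ids, cand$qid[i])
    grow <- function(m, extra_row) {
      out <- rbind(cbind(m, extra_row), c(extra_row, 0))
      dimnames(out) <- list(ids, ids)
      out
    }
    qsim <- new_similarity_matrix(grow(sim$s_blosum, qr$s_blosum[i, ]),
                                  grow(sim$s_profile, qr$s_profile[i, ]),
                                  grow(sim$s_combined, qr$s_combined[i, ]),
                                  ids,
                                  c(sim$labels, setNames("unknown", cand$qid[i])))
    classify_peptide(cand$qid[i], qsim, params, feature = "noise")
  })
  tibble(protein_id = cand$protein_id, position = cand$position,
         residue = cand$residue, kinase = ref$kinase,
         confidence = res$confidence,
         predicted = res$confidence >= threshold,
         n_pos_top_beta = res$n_pos_top_beta,
         beta = res$beta, gamma = res$gamma)
}
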