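# The indirect-relationship noise reducer: top-hit retrieval, indirect
# relationship matrix, signed weighted indirect scores and the top-beta /
# gamma decision rule.

#' Top-scoring reference peptides for a score vector
#'
#' Orders peptides by score (descending), breaking ties by peptide id
#' (ascending), and returns the first `alpha` ids. If `alpha` exceeds the
#' number of peptides it is clamped with a warning.
#'
#' @param scores Named numeric vector of similarity scores.
#' @param alpha Number of hits to return.
#' @return Character vector of peptide ids, best first.
#' @export
top_hits <- function(scores, alpha) {
  stopifnot(!is.null(names(scores)), alpha >= 1)
  if (alpha > length(scores)) {
    warn(sprintf("alpha = %d exceeds the %d available peptides; clamping",
                 alpha, length(scores)))
    alpha <- length(scores)
  }
  ord <- order(-scores, names(scores), method = "radix")
  names(scores)[ord][seq_len(alpha)]
}

#' Indirect relationship matrix
#'
#' For each of the query's top-`alpha` hits, looks up that hit's own
#' top-`alpha` reference neighbours (excluding the hit itself and the
#' query) and records their combined-similarity values; every other entry
#' is zero. Rows are hits, columns are all reference peptides. Entries are
#' never negative (a non-positive combined score carries no relationship).
#'
#' @param query_id Peptide id of the query.
#' @param sim A `similarity_matrix` covering the query and the reference.
#' @param alpha Number of hits / neighbours retained.
#' @param hits Optional explicit hit ids (default: the query's top-`alpha`
#'   by combined score).
#' @param exclude Further ids to leave out of the reference (besides the
#'   query).
#' @return Numeric matrix, `length(hits)` x `n_reference`.
#' @export
indirect_matrix <- function(query_id, sim, alpha, hits = NULL,
                            exclude = character()) {
  S <- sim$s_combined
  ref_ids <- setdiff(sim$ids, c(query_id, exclude))
  if (is.null(hits)) {
    hits <- top_hits(S[query_id, ref_ids], alpha)
  }
  M <- matrix(0, length(hits), length(ref_ids),
              dimnames = list(hits, ref_ids))
  for (j in hits) {
    partners <- setdiff(ref_ids, j)
    nb <- top_hits(S[j, partners], min(alpha, length(partners)))
    v <- S[j, nb]
    v[v < 0] <- 0
    M[j, nb] <- v
  }
  M
}

partner_weight <- function(labels, ids, weight) {
  ifelse(labels[ids] == "positive", weight, 1)
}

#' Indirect scores from a relationship matrix
#'
#' Every nonzero relationship (j, i) of the matrix is treated as signal if
#' the two peptides share a label and as noise otherwise; it contributes
#' `sign * w(partner) * value` to *both* endpoints, where the sign is +1
#' for same-label pairs and -1 for cross-label pairs, and `w` is `weight`
#' when the partner is a positive peptide and 1 otherwise. Peptides with no
#' relationships score 0.
#'
#' @param M Matrix from [indirect_matrix()] (rows = hits, columns = all
#'   reference peptides).
#' @param labels Named label vector (`"positive"`/`"negative"`).
#' @param weight Positive-partner weight (e.g. 10 for a 10:1 set).
#' @param weight_mode `"partner"` (default): the weight applies to every
#'   relationship whose partner is positive, matching the published worked
#'   example; `"pos_pairs"`: the weight applies only to positive-positive
#'   relationships.
#' @return Named numeric vector over all reference peptides (the union of
#'   the rows and columns of `M`).
#' @export
indirect_scores <- function(M, labels, weight,
                            weight_mode = c("partner", "pos_pairs")) {
  weight_mode <- match.arg(weight_mode)
  all_ids <- union(colnames(M), rownames(M))
  if (anyNA(labels[all_ids])) {
    abort("every peptide in the indirect matrix must be labelled",
          class = "phoskin_input_error")
  }
  sc <- setNames(numeric(length(all_ids)), all_ids)
  nz <- which(M != 0, arr.ind = TRUE)
  if (nrow(nz) > 0) {
    j <- rownames(M)[nz[, 1L]]
    i <- colnames(M)[nz[, 2L]]
    v <- M[nz]
    sgn <- ifelse(labels[j] == labels[i], 1, -1)
    if (weight_mode == "partner") {
      contrib_j <- sgn * partner_weight(labels, i, weight) * v
      contrib_i <- sgn * partner_weight(labels, j, weight) * v
    } else {
      pp <- labels[j] == "positive" & labels[i] == "positive"
      contrib_j <- contrib_i <- sgn * ifelse(pp, weight, 1) * v
    }
    for (k in seq_along(v)) {
      sc[j[k]] <- sc[j[k]] + contrib_j[k]
      sc[i[k]] <- sc[i[k]] + contrib_i[k]
    }
  }
  sc
}

direct_feature_matrix <- function(sim, feature) {
  switch(feature,
         blosum = sim$s_blosum,
         profile = sim$s_profile,
         combined = sim$s_combined,
         noise = sim$s_combined,
         abort(paste0("unknown feature '", feature, "'"),
               class = "phoskin_input_error"))
}

#' Classify a candidate phosphorylation site
#'
#' Runs the four-step noise-reducing decision rule for one query peptide
#' against a labelled reference set: retrieve the top-`alpha` hits by
#' combined similarity, build the indirect relationship matrix, score every
#' reference peptide by signed weighted indirect contributions, rank the
#' reference by indirect score (ties broken by direct similarity to the
#' query, then id) and inspect the top `beta`: the query is predicted
#' positive when strictly more than `gamma` of them are positive peptides,
#' with confidence = positives-in-top-beta / beta.
#'
#' With `feature` set to `"blosum"`, `"profile"` or `"combined"` the same
#' decision rule is applied to the ranking by that direct score instead
#' (the ablation baselines).
#'
#' @param query_id Query peptide id (present in `sim`, excluded from the
#'   reference).
#' @param sim A `similarity_matrix` covering query and reference.
#' @param params A [noise_params()] object.
#' @param feature `"noise"` (default), `"combined"`, `"profile"` or
#'   `"blosum"`.
#' @param exclude Further reference ids to leave out (used by the
#'   cross-validation harness).
#' @param weight_mode Passed to [indirect_scores()].
#' @return One-row tibble: `id`, `feature`, `predicted` (logical),
#'   `confidence`, `n_pos_top_beta`, `beta`, `gamma`, `tiebreak` (mean
#'   direct similarity of the top-`alpha` hits, used to order equal
#'   confidences in ROC curves).
#' @export
classify_peptide <- function(query_id, sim, params,
                             feature = c("noise", "combined", "profile",
                                         "blosum"),
                             exclude = character(),
                             weight_mode = "partner") {
  feature <- match.arg(feature)
  ref_ids <- setdiff(sim$ids, c(query_id, exclude))
  if (length(ref_ids) == 0) {
    abort("empty reference set", class = "phoskin_input_error")
  }
  labels <- sim$labels
  direct <- direct_feature_matrix(sim, feature)[query_id, ref_ids]
  comb <- sim$s_combined[query_id, ref_ids]

  alpha <- min(params$alpha, length(ref_ids))
  if (feature == "noise") {
    hits <- top_hits(comb, alpha)
    M <- indirect_matrix(query_id, sim, alpha, hits = hits,
                         exclude = exclude)
    ranking <- indirect_scores(M, labels, params$weight,
                               weight_mode = weight_mode)
    tiebreak_scores <- comb
  } else {
    ranking <- direct
    tiebreak_scores <- direct
    hits <- top_hits(direct, alpha)
  }
  beta <- params$beta
  if (beta > length(ref_ids)) {
    warn(sprintf("beta = %d exceeds the %d reference peptides; clamping",
                 beta, length(ref_ids)))
    beta <- length(ref_ids)
  }
  ord <- order(-ranking[ref_ids], -tiebreak_scores[ref_ids], ref_ids,
               method = "radix")
  top_beta <- ref_ids[ord][seq_len(beta)]
  n_pos <- sum(labels[top_beta] == "positive")
  tibble(id = query_id, feature = feature,
         predicted = n_pos > params$gamma,
         confidence = n_pos / beta,
         n_pos_top_beta = n_pos, beta = beta, gamma = params$gamma,
         tiebreak = mean(tiebreak_scores[hits]))
}
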