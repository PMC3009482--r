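# Cross-validation harness: LOOCV and stratified k-fold, confusion-count
# metrics, ROC machinery (classic AUC plus the cumulative match-count
# readout) and the four-feature ablation report.

#' Confusion counts and derived metrics
#'
#' @param truth Logical vector (`TRUE` = positive peptide).
#' @param predicted Logical vector of predictions.
#' @return One-row tibble: `tp`, `tn`, `fp`, `fn`, `acc`, `precision`,
#'   `recall`, `precision_defined` (`FALSE` when no peptide was predicted
#'   positive, in which case precision is reported as 0 and flagged).
#' @export
confusion_metrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted),
            is.logical(truth), is.logical(predicted))
  tp <- sum(truth & predicted)
  tn <- sum(!truth & !predicted)
  fp <- sum(!truth & predicted)
  fn <- sum(truth & !predicted)
  prec_def <- (tp + fp) > 0
  tibble(tp = tp, tn = tn, fp = fp, fn = fn,
         acc = (tp + tn) / (tp + tn + fp + fn),
         precision = if (prec_def) tp / (tp + fp) else 0,
         recall = if (tp + fn > 0) tp / (tp + fn) else 0,
         precision_defined = prec_def)
}

# Classify a set of queries against the reference formed by everything
# else in `sim` except the query and `exclude`; params recomputed from the
# remaining label counts unless fixed.
cv_classify <- function(sim, ref, query_ids, exclude_of, params, feature) {
  labels <- sim$labels
  purrr::map_dfr(query_ids, function(q) {
    excl <- setdiff(exclude_of(q), q)
    remaining <- setdiff(sim$ids, c(q, excl))
    p <- params
    if (is.null(p)) {
      p <- default_noise_params(sum(labels[remaining] == "positive"),
                                sum(labels[remaining] == "negative"),
                                force_weight = ref$force_weight)
    }
    res <- classify_peptide(q, sim, p, feature = feature, exclude = excl)
    res$truth <- labels[[q]] == "positive"
    res
  })
}

new_phos_cv <- function(results, feature, method, kinase, folds = NULL) {
  metrics <- confusion_metrics(results$truth, results$predicted)
  structure(list(results = results, metrics = metrics, feature = feature,
                 method = method, kinase = kinase, folds = folds),
            class = "phos_cv")
}

#' @export
print.phos_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<phos_cv> %s / feature '%s' on '%s': ACC %.3f, P %.3f%s, R %.3f (n = %d)\n",
    x$method, x$feature, x$kinase, m$acc, m$precision,
    if (m$precision_defined) "" else " (no predicted positives)",
    m$recall, nrow(x$results)))
  invisible(x)
}

#' @method tidy phos_cv
#' @export
tidy.phos_cv <- function(x, ...) x$results

#' @method glance phos_cv
#' @export
glance.phos_cv <- function(x, ...) {
  dplyr::mutate(x$metrics, feature = x$feature, method = x$method,
                kinase = x$kinase, .before = 1L)
}

#' Leave-one-out cross-validation of a reference set
#'
#' Each peptide in turn becomes the query; it is removed from the
#' reference (and from every top-hit computation), the noise parameters
#' are recomputed from the remaining label counts (unless `params` is
#' fixed), and the query is classified. Metrics are aggregated over all
#' queries.
#'
#' @param ref A `ref_set`.
#' @param params Optional fixed [noise_params()]; default: the published
#'   rules applied to the remaining counts of each fold.
#' @param feature Score level to evaluate: `"noise"` (default),
#'   `"combined"`, `"profile"` or `"blosum"`.
#' @param sim Optional precomputed [similarity_matrix()] for `ref`.
#' @return Object of class `phos_cv`; see [tidy()] / [glance()].
#' @export
loocv <- function(ref, params = NULL, feature = "noise", sim = NULL) {
  if (sum(ref$peptides$label == "positive") < 2) {
    abort("LOOCV needs at least two positive peptides",
          class = "phoskin_input_error")
  }
  if (is.null(sim)) sim <- similarity_matrix(ref)
  results <- cv_classify(sim, ref, ref$peptides$id,
                         exclude_of = function(q) character(),
                         params = params, feature = feature)
  new_phos_cv(results, feature, "loocv", ref$kinase)
}

# Continuous round-robin fold assignment, stratified by label: per-class
# fold sizes differ by at most one, and k = n degenerates to one peptide
# per fold (LOOCV).
stratified_folds <- function(labels, k, seed) {
  ids <- names(labels)
  withr::with_seed(seed, {
    assignment <- setNames(integer(length(ids)), ids)
    counter <- 0L
    for (lab in c("positive", "negative")) {
      members <- sample(ids[labels == lab])
      assignment[members] <- ((counter + seq_along(members) - 1L) %% k) + 1L
      counter <- counter + length(members)
    }
    assignment
  })
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by label so the negative:positive ratio is
#' preserved (per-class fold sizes differ by at most one); each fold is
#' classified against the union of the other folds. Both pooled metrics
#' (confusion counts summed over folds) and per-fold metrics with their
#' mean are reported. With `k` equal to the number of peptides this
#' reduces to LOOCV.
#'
#' @inheritParams loocv
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold shuffle.
#' @return Object of class `phos_cv` with a `folds` element (per-fold
#'   metrics and their mean).
#' @export
kfold_cv <- function(ref, k = 10L, params = NULL, feature = "noise",
                     seed = 1L, sim = NULL) {
  labels <- ref_labels(ref)
  n_class <- table(labels)
  if (k < 2) abort("k must be at least 2", class = "phoskin_input_error")
  if (k > length(labels) || (k > min(n_class) && k != length(labels))) {
    abort(sprintf("k = %d exceeds the smaller class (%d peptides)",
                  k, min(n_class)), class = "phoskin_input_error")
  }
  if (is.null(sim)) sim <- similarity_matrix(ref)
  fold_of <- stratified_folds(labels, k, seed)
  results <- cv_classify(sim, ref, ref$peptides$id,
                         exclude_of = function(q) {
                           names(fold_of)[fold_of == fold_of[[q]]]
                         },
                         params = params, feature = feature)
  results$fold <- fold_of[results$id]
  per_fold <- results |>
    dplyr::group_by(.data$fold) |>
    dplyr::group_modify(~ confusion_metrics(.x$truth, .x$predicted)) |>
    dplyr::ungroup()
  folds <- list(per_fold = per_fold,
                mean = dplyr::summarise(per_fold,
                                        acc = mean(.data$acc),
                                        precision = mean(.data$precision),
                                        recall = mean(.data$recall)))
  new_phos_cv(results, feature, sprintf("%d-fold", k), ref$kinase,
              folds = folds)
}

#' ROC curve over ranked queries
#'
#' Queries are ranked by score (descending; exact ties step all at once,
#' the Mann-Whitney convention, with optional lexicographic tie-breaking
#' by `tiebreak`). Returns the cumulative (false-match, true-match) count
#' curve -- the plot of true positives as a function of the number of
#' false positives -- and the area under it normalised to the unit range.
#'
#' @param scores Numeric ranking scores, one per query.
#' @param truth Logical vector (`TRUE` = positive).
#' @param tiebreak Optional secondary score used to order equal primary
#'   scores before ties are declared.
#' @return Object of class `phos_roc`: tibble `points` with columns
#'   `fp_count`, `tp_count`, `score`, plus `auc`, `n_pos`, `n_neg`.
#' @export
roc_points <- function(scores, truth, tiebreak = NULL) {
  stopifnot(length(scores) == length(truth), is.logical(truth))
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC needs at least one positive and one negative query",
          class = "phoskin_input_error")
  }
  if (is.null(tiebreak)) tiebreak <- numeric(length(scores))
  ord <- order(-scores, -tiebreak, method = "radix")
  s <- scores[ord]
  tb <- tiebreak[ord]
  t <- truth[ord]
  new_group <- c(TRUE, s[-1] != s[-length(s)] | tb[-1] != tb[-length(tb)])
  grp <- cumsum(new_group)
  tp <- unname(tapply(t, grp, sum))
  fp <- unname(tapply(!t, grp, sum))
  pts <- tibble(fp_count = cumsum(fp), tp_count = cumsum(tp),
                score = unname(tapply(s, grp, `[`, 1L)))
  # Mann-Whitney AUC with the half-credit tie convention, computed by
  # trapezoid over the tie-grouped step curve anchored at the origin.
  x <- c(0, pts$fp_count)
  y <- c(0, pts$tp_count)
  auc <- sum(diff(x) * (y[-length(y)] + y[-1]) / 2) / (n_pos * n_neg)
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "phos_roc")
}

#' @export
print.phos_roc <- function(x, ...) {
  cat(sprintf("<phos_roc> AUC %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @method tidy phos_roc
#' @export
tidy.phos_roc <- function(x, ...) x$points

#' True matches recovered up to a false-match budget
#'
#' The cumulative match-count readout: how many true phosphopeptides are
#' ranked above the threshold at which `n_false` non-phosphopeptides have
#' been admitted.
#'
#' @param roc A `phos_roc`.
#' @param n_false Maximum number of false matches.
#' @return Integer count of true matches.
#' @export
true_matches_at <- function(roc, n_false) {
  pts <- roc$points
  ok <- pts$fp_count <= n_false
  if (!any(ok)) return(0L)
  as.integer(max(pts$tp_count[ok]))
}

#' @method autoplot phos_roc
#' @export
autoplot.phos_roc <- function(object, ...) {
  df <- dplyr::bind_rows(tibble(fp_count = 0, tp_count = 0,
                                score = Inf),
                         object$points)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fp_count, y = .data$tp_count)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "false matches", y = "true matches",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' ROC from a cross-validation result
#'
#' Ranks queries by confidence, breaking ties by the mean direct combined
#' similarity of each query's top hits.
#'
#' @param cv A `phos_cv`.
#' @return A `phos_roc`.
#' @export
cv_roc <- function(cv) {
  roc_points(cv$results$confidence, cv$results$truth,
             tiebreak = cv$results$tiebreak)
}

#' Four-feature ablation report
#'
#' Runs LOOCV at each of the four score levels (windowed BLOSUM62 score,
#' profile alignment score, their product, and the noise-reducing
#' classifier) and tabulates accuracy, precision and recall.
#'
#' @inheritParams loocv
#' @return Object of class `phos_ablation`: tibble with one row per
#'   feature, plus the per-feature `phos_cv` objects in `$cv`.
#' @export
ablation <- function(ref, params = NULL, sim = NULL) {
  if (is.null(sim)) sim <- similarity_matrix(ref)
  features <- c("blosum", "profile", "combined", "noise")
  cvs <- purrr::map(features, function(f) {
    loocv(ref, params = params, feature = f, sim = sim)
  })
  names(cvs) <- features
  report <- purrr::map_dfr(cvs, glance)
  structure(list(report = report, cv = cvs, kinase = ref$kinase),
            class = "phos_ablation")
}

#' @export
print.phos_ablation <- function(x, ...) {
  cat(sprintf("<phos_ablation> kinase '%s'\n", x$kinase))
  print(as.data.frame(x$report[c("feature", "acc", "precision", "recall")]),
        row.names = FALSE)
  invisible(x)
}

#' @method tidy phos_ablation
#' @export
tidy.phos_ablation <- function(x, ...) x$report

#' @method autoplot phos_ablation
#' @export
autoplot.phos_ablation <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$report[c("feature", "acc", "precision", "recall")],
    cols = c("acc", "precision", "recall"),
    names_to = "metric", values_to = "value")
  df$feature <- factor(df$feature,
                       levels = c("blosum", "profile", "combined", "noise"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("LOOCV ablation: %s", object$kinase)) +
    ggplot2::theme_minimal()
}
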