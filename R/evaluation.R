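# Evaluation: FPR at fixed recall, ROC-AUC, balanced accuracy, MC-vs-naive
# disagreement, inter-assay correlation, permutation feature importance.

drop_missing <- function(scores, labels) {
  obs <- !is.na(labels)
  list(scores = scores[obs], labels = as.numeric(labels[obs]), n = sum(obs))
}

#' False-positive rate at a fixed recall
#'
#' Over the empirical step-function ROC of distinct score thresholds (a
#' prediction is positive when `score >= threshold`; tied scores collapse
#' into a single operating point), returns the minimum FPR among operating
#' points with TPR at least `tpr_target`, together with the largest threshold
#' achieving it. No interpolation between operating points. Missing labels
#' are excluded.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels over `{1, 0, NA}`.
#' @param tpr_target Required recall (default 0.9).
#' @return List with `fpr`, `threshold`, `tpr` (achieved recall) and
#'   `n_evaluated`; `fpr` is `NA` with a `reason` when there is no positive
#'   (or no negative) among the non-missing labels.
#' @export
fpr_at_tpr <- function(scores, labels, tpr_target = 0.9) {
  z <- drop_missing(scores, labels)
  n1 <- sum(z$labels == 1); n0 <- sum(z$labels == 0)
  if (n1 == 0 || n0 == 0) {
    return(list(fpr = NA_real_, threshold = NA_real_, tpr = NA_real_,
                n_evaluated = z$n,
                reason = if (n1 == 0) "no positive labels" else "no negative labels"))
  }
  thr <- sort(unique(z$scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(z$scores >= t & z$labels == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(z$scores >= t & z$labels == 0), numeric(1))
  tpr <- tp / n1; fpr <- fp / n0
  ok <- tpr >= tpr_target
  best <- min(fpr[ok])
  cand <- which(ok & fpr == best)
  pick <- cand[which.max(thr[cand])]
  list(fpr = best, threshold = thr[pick], tpr = tpr[pick], n_evaluated = z$n)
}

#' ROC-AUC (Mann-Whitney formulation)
#'
#' Probability that a random positive outscores a random negative, with tied
#' scores counted half. Missing labels are excluded; invariant to strictly
#' monotone transforms of the scores.
#'
#' @inheritParams fpr_at_tpr
#' @return AUC in `[0, 1]`, or `NA` when a class is absent.
#' @export
roc_auc <- function(scores, labels) {
  z <- drop_missing(scores, labels)
  n1 <- sum(z$labels == 1); n0 <- sum(z$labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(z$scores)              # average ranks handle ties as half
  (sum(r[z$labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Balanced accuracy at a threshold
#'
#' `(sensitivity + specificity) / 2` with predictions `score >= threshold`;
#' missing labels are excluded.
#'
#' @inheritParams fpr_at_tpr
#' @param threshold Classification threshold (default 0.5).
#' @export
balanced_accuracy <- function(scores, labels, threshold = 0.5) {
  z <- drop_missing(scores, labels)
  pred <- as.integer(z$scores >= threshold)
  n1 <- sum(z$labels == 1); n0 <- sum(z$labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  sens <- sum(pred == 1 & z$labels == 1) / n1
  spec <- sum(pred == 0 & z$labels == 0) / n0
  (sens + spec) / 2
}

#' Disagreement rate between two sets of class calls
#'
#' Fraction of chemicals whose predicted class differs between two
#' approaches (e.g. Monte Carlo vs the fixed-threshold baseline), per assay
#' when matrices are supplied.
#'
#' @param a,b Class vectors or chemicals x assays matrices over `{0, 1}`.
#' @return Fraction (per assay for matrices).
#' @export
disagreement_rate <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (is.matrix(a)) colMeans(a != b) else mean(a != b)
}

#' Pairwise inter-assay label correlation
#'
#' Phi coefficient (Pearson on 0/1) per assay pair over the chemicals with
#' both labels observed; the diagonal is 1 and pairs with fewer than `min_n`
#' overlapping chemicals are reported missing.
#'
#' @param labels Label matrix over `{1, 0, NA}`.
#' @param min_n Minimum pairwise overlap (default 10).
#' @return Assay x assay correlation matrix.
#' @export
assay_correlation <- function(labels, min_n = 10) {
  validate_labels(labels)
  A <- ncol(labels)
  out <- matrix(NA_real_, A, A, dimnames = list(colnames(labels), colnames(labels)))
  diag(out) <- 1
  for (i in seq_len(A)) for (j in seq_len(A)) {
    if (j <= i) next
    ok <- !is.na(labels[, i]) & !is.na(labels[, j])
    if (sum(ok) < min_n) next
    r <- suppressWarnings(stats::cor(labels[ok, i], labels[ok, j]))
    out[i, j] <- out[j, i] <- if (is.finite(r)) r else NA_real_
  }
  out
}

#' Permutation feature importance
#'
#' For each feature, the drop in a metric after shuffling that column of the
#' input (breaking its association with the labels while preserving its
#' marginal), averaged over `n_repeats` shuffles. Features are ranked by mean
#' drop, descending, ties broken by feature id. A model-agnostic attribution
#' that flags the planted toxicophores a model actually uses.
#'
#' @param model Model honouring the [predict_scores()] contract.
#' @param x Feature matrix.
#' @param y Labels for one assay (`{1, 0, NA}`).
#' @param metric Function `(scores, labels) -> scalar`, larger is better
#'   (default [roc_auc()]).
#' @param n_repeats Shuffles per feature (default 5).
#' @param assay For multi-output models, the assay (index or name) whose
#'   output is evaluated.
#' @param seed Integer seed.
#' @return data.frame with `feature_id`, `mean_drop`, `sd_drop`, `rank`,
#'   sorted by decreasing importance; the baseline metric is attached as an
#'   attribute.
#' @export
permutation_importance <- function(model, x, y, metric = roc_auc,
                                   n_repeats = 5, assay = 1, seed = 1) {
  x <- align_features(x, model$feature_ids)
  set.seed(child_seed(seed, "permutation_importance"))
  get_col <- function(s) if (is.matrix(s)) s[, assay] else s
  baseline <- metric(get_col(predict_scores(model, x)), y)
  n <- nrow(x)
  drops <- matrix(NA_real_, ncol(x), n_repeats,
                  dimnames = list(colnames(x), NULL))
  for (j in seq_len(ncol(x))) {
    for (r in seq_len(n_repeats)) {
      xp <- x
      xp[, j] <- x[sample.int(n), j]
      drops[j, r] <- baseline - metric(get_col(predict_scores(model, xp)), y)
    }
  }
  out <- data.frame(feature_id = colnames(x),
                    mean_drop = rowMeans(drops),
                    sd_drop = apply(drops, 1, stats::sd),
                    row.names = NULL)
  out <- out[order(-out$mean_drop, out$feature_id), ]
  out$rank <- seq_len(nrow(out))
  attr(out, "baseline") <- baseline
  out
}

#' Per-assay evaluation report
#'
#' Computes [fpr_at_tpr()], [roc_auc()] and [balanced_accuracy()] per assay
#' from a score matrix and a label matrix, excluding missing labels; the
#' number of evaluated (non-missing) labels is reported per assay.
#'
#' @param scores Chemicals x assays score matrix (or vector for one assay).
#' @param labels Matching label matrix over `{1, 0, NA}`.
#' @param tpr_target Recall target for the FPR metric (default 0.9).
#' @param class_threshold Threshold for balanced accuracy (default 0.5).
#' @return data.frame, one row per assay: `assay`, `fpr_at_tpr`,
#'   `operating_threshold`, `roc_auc`, `balanced_accuracy`, `n_evaluated`.
#' @export
eval_report <- function(scores, labels, tpr_target = 0.9, class_threshold = 0.5) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  stopifnot(identical(dim(scores), dim(labels)))
  assays <- colnames(labels) %||% make_ids("assay", ncol(labels))
  rows <- lapply(seq_len(ncol(labels)), function(a) {
    f <- fpr_at_tpr(scores[, a], labels[, a], tpr_target)
    data.frame(assay = assays[a],
               tpr_target = tpr_target,
               fpr_at_tpr = f$fpr,
               operating_threshold = f$threshold,
               roc_auc = roc_auc(scores[, a], labels[, a]),
               balanced_accuracy = balanced_accuracy(scores[, a], labels[, a],
                                                     class_threshold),
               n_evaluated = f$n_evaluated,
               row.names = NULL)
  })
  do.call(rbind, rows)
}
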