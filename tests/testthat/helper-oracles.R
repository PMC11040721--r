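# Independent brute-force oracles used to verify the package's metric,
# filtering and partitioning implementations. These deliberately use naive
# enumeration, not the code paths they check.

# FPR at fixed recall by exhaustive threshold enumeration (>= convention,
# ties naturally grouped because thresholds are taken from the score set)
oracle_fpr_at_tpr <- function(scores, labels, tpr_target = 0.9) {
  obs <- !is.na(labels)
  scores <- scores[obs]; labels <- labels[obs]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  best <- Inf
  for (t in unique(scores)) {
    pred <- scores >= t
    tpr <- sum(pred & labels == 1) / n1
    fpr <- sum(pred & labels == 0) / n0
    if (tpr >= tpr_target && fpr < best) best <- fpr
  }
  best
}

# ROC-AUC by direct pairwise counting, ties half
oracle_roc_auc <- function(scores, labels) {
  obs <- !is.na(labels)
  s1 <- scores[obs][labels[obs] == 1]
  s0 <- scores[obs][labels[obs] == 0]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

oracle_balanced_accuracy <- function(scores, labels, threshold = 0.5) {
  obs <- !is.na(labels)
  pred <- as.integer(scores[obs] >= threshold)
  y <- labels[obs]
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

# independent re-implementation of the greedy correlation filter
oracle_filter_correlated <- function(table, cutoff) {
  keep <- colnames(table)
  repeat {
    cm <- suppressWarnings(abs(cor(table[, keep, drop = FALSE])))
    cm[!is.finite(cm)] <- 0
    diag(cm) <- 0
    if (length(keep) < 2 || max(cm) <= cutoff) break
    hit <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    i <- keep[hit[1]]; j <- keep[hit[2]]
    mi <- mean(cm[hit[1], -hit[1]]); mj <- mean(cm[hit[2], -hit[2]])
    drop_id <- if (mi > mj) i else if (mj > mi) j else
      c(i, j)[which.min(match(c(i, j), colnames(table)))]
    keep <- setdiff(keep, drop_id)
  }
  keep
}

# total within-group pairwise squared Euclidean distance, computed directly
oracle_diversity <- function(x, groups) {
  sum(sapply(unique(groups), function(g) {
    xs <- x[groups == g, , drop = FALSE]
    sum(dist(xs)^2)
  }))
}

# best balanced 2-partition of n points by exhaustive enumeration
oracle_best_balanced_2partition <- function(x) {
  n <- nrow(x)
  half <- n / 2
  sets <- combn(n, half)
  best <- -Inf
  for (k in seq_len(ncol(sets))) {
    g <- rep(2L, n); g[sets[, k]] <- 1L
    best <- max(best, oracle_diversity(x, g))
  }
  best
}

# exact expectation of a model score under independent Bernoulli features,
# by direct summation over completions (independent of the package's
# brute_force_expectation)
oracle_expectation <- function(score_fun, p) {
  d <- length(p)
  tot <- 0
  for (k in 0:(2^d - 1)) {
    bits <- as.integer(intToBits(k))[1:d]
    w <- prod(ifelse(bits == 1, p, 1 - p))
    tot <- tot + w * score_fun(bits)
  }
  tot
}
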