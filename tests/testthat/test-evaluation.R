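# Metrics against brute-force oracles, disagreement, assay correlation,
# permutation importance.

test_that("FPR at fixed recall handles the canonical edge cases", {
  # perfect separation
  s <- c(0.9, 0.8, 0.2, 0.1); y <- c(1, 1, 0, 0)
  expect_equal(fpr_at_tpr(s, y)$fpr, 0)
  # constant scores force the all-positive operating point
  expect_equal(fpr_at_tpr(rep(0.3, 10), c(rep(1, 3), rep(0, 7)))$fpr, 1)
  # no positives reported as missing with a reason
  r <- fpr_at_tpr(runif(5), rep(0, 5))
  expect_true(is.na(r$fpr))
  expect_match(r$reason, "no positive")
})

test_that("metrics agree exactly with brute-force oracles on random instances", {
  set.seed(1)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    # ties are likely: scores on a coarse grid
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    y <- sample(c(0, 1, NA), n, replace = TRUE, prob = c(0.5, 0.4, 0.1))
    if (sum(y == 1, na.rm = TRUE) == 0 || sum(y == 0, na.rm = TRUE) == 0) next
    tt <- sample(c(0.5, 0.8, 0.9, 1), 1)
    expect_identical(fpr_at_tpr(s, y, tt)$fpr, oracle_fpr_at_tpr(s, y, tt))
    expect_equal(roc_auc(s, y), oracle_roc_auc(s, y), tolerance = 1e-12)
    expect_identical(balanced_accuracy(s, y), oracle_balanced_accuracy(s, y))
  }
})

test_that("the returned operating threshold reproduces the returned FPR", {
  set.seed(2)
  s <- runif(30); y <- rbinom(30, 1, 0.4)
  r <- fpr_at_tpr(s, y, 0.9)
  pred <- s >= r$threshold
  expect_equal(sum(pred & y == 0) / sum(y == 0), r$fpr)
  expect_gte(sum(pred & y == 1) / sum(y == 1), 0.9)
})

test_that("FPR at fixed recall is monotone in the recall target", {
  set.seed(3)
  s <- runif(50); y <- rbinom(50, 1, 0.3)
  fprs <- vapply(c(0.5, 0.7, 0.9, 1), function(tt)
    fpr_at_tpr(s, y, tt)$fpr, numeric(1))
  expect_true(all(diff(fprs) >= 0))
})

test_that("ROC-AUC is invariant to strictly monotone score transforms", {
  set.seed(4)
  s <- runif(40); y <- rbinom(40, 1, 0.5)
  a <- roc_auc(s, y)
  expect_equal(roc_auc(qlogis(s * 0.98 + 0.01), y), a)
  expect_equal(roc_auc(s^3, y), a)
  expect_equal(roc_auc(rank(s), y), a)
  # perfect and reversed rankings
  expect_equal(roc_auc(y + 0, y), 1)
  expect_equal(roc_auc(1 - y, y), 0)
})

test_that("ROC-AUC matches the pROC reference on tied and untied scores", {
  skip_if_not_installed("pROC")
  set.seed(5)
  for (i in 1:10) {
    s <- sample(seq(0, 1, 0.05), 50, replace = TRUE)
    y <- rbinom(50, 1, 0.4)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    expect_equal(roc_auc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("balanced accuracy follows the 2x2 table arithmetic", {
  # 3/4 sensitivity, 4/5 specificity
  s <- c(0.9, 0.8, 0.7, 0.1, 0.4, 0.3, 0.2, 0.1, 0.6)
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0)
  expect_equal(balanced_accuracy(s, y), (3 / 4 + 4 / 5) / 2)
  set.seed(6)
  yr <- rbinom(4000, 1, 0.5)
  expect_equal(balanced_accuracy(runif(4000), yr), 0.5, tolerance = 0.05)
})

test_that("disagreement rate counts differing class calls", {
  expect_identical(disagreement_rate(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_identical(disagreement_rate(c(1, 0), c(0, 1)), 1)
  expect_equal(disagreement_rate(rep(1, 10), c(rep(0, 3), rep(1, 7))), 0.3)
  m1 <- matrix(c(1, 0, 1, 1), 2, 2, dimnames = list(NULL, c("a", "b")))
  m2 <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(disagreement_rate(m1, m2)), c(0.5, 0))
})

test_that("assay correlation recovers independence and induced correlation", {
  fp <- generate_fingerprints(10000, 30, seed = 7)
  # truly independent assays: separate models on disjoint feature blocks
  m1 <- plant_toxicophores(fp[, 1:15], 1, 4, 2, target_prevalence = 0.2, seed = 7)
  m2 <- plant_toxicophores(fp[, 16:30], 1, 4, 2, target_prevalence = 0.2, seed = 17)
  lab_ind <- cbind(simulate_labels(fp[, 1:15], m1, seed = 8),
                   simulate_labels(fp[, 16:30], m2, seed = 18))
  colnames(lab_ind) <- c("assay_0001", "assay_0002")
  shared <- plant_toxicophores(fp, 2, 4, 2, share_fraction = 1,
                               target_prevalence = 0.2, seed = 7)
  lab_sh <- simulate_labels(fp, shared, seed = 8)
  ci <- assay_correlation(lab_ind)
  cs <- assay_correlation(lab_sh)
  expect_equal(diag(ci), c(assay_0001 = 1, assay_0002 = 1))
  expect_lt(abs(ci[1, 2]), 0.05)
  expect_gt(cs[1, 2], 0.1)
  # insufficient overlap reported missing
  lab_na <- lab_ind
  lab_na[1:9995, 1] <- NA
  expect_true(is.na(assay_correlation(lab_na, min_n = 10)[1, 2]))
})

test_that("permutation importance ranks the causal feature first, ignored ones last", {
  set.seed(9)
  x <- matrix(rbinom(3000, 1, 0.5), 1000, 3,
              dimnames = list(NULL, c("causal", "noise1", "noise2")))
  y <- rbinom(1000, 1, plogis(3 * x[, "causal"] - 1.5))
  m <- train_single_output(x, y, "random_forest", seed = 10)
  imp <- permutation_importance(m, x, y, n_repeats = 3, seed = 11)
  expect_identical(imp$feature_id[1], "causal")
  expect_lt(max(abs(imp$mean_drop[imp$feature_id != "causal"])), 0.05)
  # reproducible per seed
  imp2 <- permutation_importance(m, x, y, n_repeats = 3, seed = 11)
  expect_identical(imp, imp2)
})

test_that("eval_report aggregates per assay and counts evaluated labels", {
  set.seed(12)
  s <- matrix(runif(200), 100, 2, dimnames = list(NULL, c("a1", "a2")))
  y <- matrix(sample(c(0L, 1L, NA), 200, replace = TRUE), 100, 2,
              dimnames = list(sprintf("c%03d", 1:100), c("a1", "a2")))
  rep <- eval_report(s, y)
  expect_identical(rep$assay, c("a1", "a2"))
  expect_equal(rep$n_evaluated, unname(colSums(!is.na(y))))
  expect_equal(rep$roc_auc[1], roc_auc(s[, 1], y[, 1]))
  expect_equal(rep$fpr_at_tpr[2], fpr_at_tpr(s[, 2], y[, 2])$fpr)
})
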