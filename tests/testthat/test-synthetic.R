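# Synthetic generator: calibration, correlation structure, determinism.

test_that("independent fingerprints match their configured prevalence", {
  fp <- generate_fingerprints(10000, 8, rho = 0, prevalence_range = c(0.5, 0.5),
                              seed = 42)
  expect_true(all(colMeans(fp) > 0.47 & colMeans(fp) < 0.53))
  cm <- cor(fp)
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.05)
})

test_that("within-block latent correlation matches the tetrachoric mapping", {
  fp <- generate_fingerprints(5000, 5, n_blocks = 1, rho = 0.95,
                              prevalence_range = c(0.5, 0.5), seed = 7)
  cm <- cor(fp)
  expect_gt(min(cm[upper.tri(cm)]), 0.5)
  # at prevalence 1/2 the implied phi is (2/pi) * asin(rho)
  expect_equal(mean(cm[upper.tri(cm)]), 2 / pi * asin(0.95), tolerance = 0.03)
})

test_that("fingerprint generation is deterministic per seed and rejects bad rho", {
  a <- generate_fingerprints(50, 10, n_blocks = 2, rho = 0.4, seed = 3)
  b <- generate_fingerprints(50, 10, n_blocks = 2, rho = 0.4, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, generate_fingerprints(50, 10, n_blocks = 2,
                                                  rho = 0.4, seed = 4)))
  expect_error(generate_fingerprints(50, 10, rho = 1), "rho")
  expect_error(generate_fingerprints(50, 10, rho = -0.1), "rho")
})

test_that("planted model has exact sparsity and calibrated intercepts", {
  fp <- generate_fingerprints(2000, 100, seed = 1)
  pm <- plant_toxicophores(fp, n_assays = 4, sparsity = 3, effect_size = 1.5,
                           target_prevalence = 0.05, seed = 2)
  expect_true(all(colSums(pm$weights != 0) == 3))
  prev <- colMeans(plogis(sweep(fp %*% pm$weights, 2, pm$intercepts, `+`)))
  expect_true(all(abs(prev - 0.05) <= 0.002))
})

test_that("zero effect size gives the closed-form logit intercept", {
  fp <- generate_fingerprints(1000, 20, seed = 1)
  pm <- plant_toxicophores(fp, n_assays = 2, sparsity = 3, effect_size = 0,
                           target_prevalence = 0.05, seed = 2)
  expect_true(all(abs(pm$intercepts - qlogis(0.05)) < 0.01))
})

test_that("fully shared toxicophores give positively phi-correlated labels", {
  fp <- generate_fingerprints(50000, 40, seed = 5)
  phis <- sapply(c(0, 0.5, 1), function(sf) {
    pm <- plant_toxicophores(fp, n_assays = 2, sparsity = 5, effect_size = 2,
                             share_fraction = sf, target_prevalence = 0.1,
                             seed = 6)
    lab <- simulate_labels(fp, pm, seed = 7)
    if (sf == 1) {
      expect_identical(which(pm$weights[, 1] != 0), which(pm$weights[, 2] != 0))
    }
    cor(lab[, 1], lab[, 2])
  })
  expect_gt(phis[3], 0)
  # label correlation is non-decreasing in the shared fraction
  expect_true(all(diff(phis) >= -0.01))
  expect_gt(phis[3], phis[1] + 0.05)
})

test_that("simulated labels match prevalence and missingness closed forms", {
  fp <- generate_fingerprints(10000, 30, seed = 1)
  pm <- plant_toxicophores(fp, n_assays = 12, sparsity = 4, effect_size = 1,
                           target_prevalence = 0.05, seed = 2)
  lab0 <- simulate_labels(fp, pm, missing_rate = 0, seed = 3)
  expect_false(anyNA(lab0))
  act <- colMeans(lab0)
  expect_true(all(abs(act - 0.05) <= 0.01))

  lab <- simulate_labels(fp, pm, missing_rate = 0.164, seed = 3)
  frac_any_missing <- mean(rowSums(is.na(lab)) >= 1)
  expect_equal(frac_any_missing, 1 - (1 - 0.164)^12, tolerance = 0.025)
  act2 <- colSums(lab == 1, na.rm = TRUE) / colSums(!is.na(lab))
  expect_true(all(abs(act2 - 0.05) <= 0.01))
})

test_that("duplicate injection counts and recovery behave as configured", {
  fp <- generate_fingerprints(1000, 10, seed = 1)
  pm <- plant_toxicophores(fp, 2, 2, 1, target_prevalence = 0.2, seed = 2)
  lab <- simulate_labels(fp, pm, missing_rate = 0.1, seed = 3)

  none <- inject_duplicates(lab, dup_fraction = 0, seed = 4)
  expect_equal(nrow(none), 1000)
  expect_identical(deduplicate(none), lab)

  rec <- inject_duplicates(lab, dup_fraction = 0.3, flip_prob = 0, copies = 2,
                           seed = 4)
  expect_equal(nrow(rec), 1300)
  expect_identical(deduplicate(rec), lab)  # flip_prob = 0 recovers ground truth

  noisy <- inject_duplicates(lab, dup_fraction = 0.3, flip_prob = 0.5,
                             copies = 2, seed = 4)
  expect_false(identical(deduplicate(noisy), lab))
})

test_that("probabilistic fingerprints reproduce per-feature error rates", {
  fp <- generate_fingerprints(5000, 10, prevalence_range = c(0.3, 0.7), seed = 1)
  spec <- reliability_spec(colnames(fp), error_range = c(0.04, 0.04),
                           hard_fraction = 0, seed = 2)
  probs <- emulate_probabilistic_fingerprints(fp, spec, seed = 3)
  expect_true(all(probs >= 0 & probs <= 1))
  err <- colMeans((probs >= 0.5) != (fp == 1))
  expect_lt(abs(mean(err) - 0.04), 0.01)
  expect_true(all(abs(err - 0.04) <= 0.02))
})

test_that("a hard feature shows its elevated error while others stay at baseline", {
  fp <- generate_fingerprints(5000, 6, prevalence_range = c(0.3, 0.7), seed = 1)
  spec <- reliability_spec(colnames(fp), error_range = c(0.03, 0.03),
                           hard_fraction = 0, seed = 2)
  spec$error["fp_0004"] <- 0.12
  probs <- emulate_probabilistic_fingerprints(fp, spec, seed = 3)
  err <- colMeans((probs >= 0.5) != (fp == 1))
  expect_equal(unname(err["fp_0004"]), 0.12, tolerance = 0.02)
  expect_true(all(abs(err[names(err) != "fp_0004"] - 0.03) <= 0.015))
})

test_that("degenerate noiseless mode emits the bits themselves", {
  fp <- generate_fingerprints(100, 5, seed = 1)
  spec <- reliability_spec(colnames(fp), error_range = c(0, 0),
                           hard_fraction = 0, shape = c(Inf, Inf), seed = 2)
  probs <- emulate_probabilistic_fingerprints(fp, spec, seed = 3)
  expect_equal(unname(probs), unname(fp + 0))
})

test_that("every generator op is deterministic for fixed inputs and seed", {
  fp <- generate_fingerprints(200, 15, seed = 9)
  pm1 <- plant_toxicophores(fp, 2, 3, 1, target_prevalence = 0.1, seed = 9)
  pm2 <- plant_toxicophores(fp, 2, 3, 1, target_prevalence = 0.1, seed = 9)
  expect_identical(pm1, pm2)
  lab <- simulate_labels(fp, pm1, 0.2, seed = 9)
  expect_identical(lab, simulate_labels(fp, pm1, 0.2, seed = 9))
  spec <- reliability_spec(colnames(fp), seed = 9)
  expect_identical(emulate_probabilistic_fingerprints(fp, spec, seed = 9),
                   emulate_probabilistic_fingerprints(fp, spec, seed = 9))
  expect_identical(inject_duplicates(lab, 0.2, 0.3, seed = 9),
                   inject_duplicates(lab, 0.2, 0.3, seed = 9))
})
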