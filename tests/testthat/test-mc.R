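# Monte Carlo inference: sampling, estimator correctness against the
# enumeration oracle, the naive baseline, and convergence behaviour.

toy_model <- function(d, seed) {
  set.seed(seed)
  linear_scorer(setNames(rnorm(d, sd = 1.5), sprintf("f%d", seq_len(d))),
                rnorm(1))
}

test_that("Bernoulli sampling is calibrated, deterministic, and validated", {
  p <- rep(0.5, 6)
  x <- sample_binary_vectors(p, 10000, seed = 1)
  expect_true(all(abs(colMeans(x) - 0.5) < 0.015))  # 3 sigma at N = 10000
  expect_identical(x, sample_binary_vectors(p, 10000, seed = 1))
  # degenerate probabilities force identical vectors
  pd <- c(1, 0, 1, 1, 0)
  xd <- sample_binary_vectors(pd, 50, seed = 2)
  expect_true(all(xd == matrix(pd, 50, 5, byrow = TRUE)))
  expect_error(sample_binary_vectors(c(0.5, 1.2), 10), "\\[0, 1\\]")
})

test_that("the MC mean tracks the enumeration oracle within 3 SE", {
  mod <- toy_model(8, seed = 3)
  set.seed(4)
  p <- setNames(runif(8), mod$feature_ids)
  exact <- brute_force_expectation(mod, p)
  # the enumeration oracle itself agrees with direct hand summation
  direct <- oracle_expectation(function(bits)
    plogis(sum(bits * mod$weights) + mod$intercept), p)
  expect_equal(exact, unname(direct), tolerance = 1e-12)
  mc <- predict_monte_carlo(mod, p, N = 10000, seed = 5)
  expect_lt(abs(mc$mean_score - exact), 3 * mc$se + 1e-12)
})

test_that("degenerate probabilities give the exact single-vector score", {
  mod <- toy_model(6, seed = 6)
  p <- setNames(c(1, 0, 1, 0, 0, 1), mod$feature_ids)
  mc <- predict_monte_carlo(mod, p, N = 37, seed = 7)
  nv <- predict_naive(mod, p)
  expect_identical(unname(mc$mean_score), unname(nv$score))
  expect_identical(mc$se, 0)
})

test_that("a model ignoring all features is constant in p", {
  mod <- linear_scorer(setNames(rep(0, 5), sprintf("f%d", 1:5)), 0.7)
  s1 <- predict_monte_carlo(mod, setNames(runif(5), mod$feature_ids),
                            N = 200, seed = 8)$mean_score
  s2 <- predict_monte_carlo(mod, setNames(runif(5), mod$feature_ids),
                            N = 200, seed = 9)$mean_score
  expect_equal(unname(s1), plogis(0.7))
  expect_identical(s1, s2)
})

test_that("checkpointed running means are prefix-consistent", {
  mod <- toy_model(7, seed = 10)
  p <- setNames(runif(7), mod$feature_ids)
  big <- predict_monte_carlo(mod, p, N = 5000, checkpoints = c(100, 1000),
                             seed = 11)
  for (n in c(100, 1000)) {
    fresh <- predict_monte_carlo(mod, p, N = n, seed = 11)
    expect_equal(unname(big$checkpoints[as.character(n), ]),
                 unname(fresh$mean_score))
  }
})

test_that("the MC estimator is unbiased over independent runs", {
  mod <- toy_model(6, seed = 12)
  set.seed(13)
  p <- setNames(runif(6), mod$feature_ids)
  exact <- brute_force_expectation(mod, p)
  runs <- vapply(1:40, function(s)
    predict_monte_carlo(mod, p, N = 500, seed = s)$mean_score, numeric(1))
  se_mean <- sd(runs) / sqrt(length(runs))
  expect_lt(abs(mean(runs) - exact), 3 * se_mean)
})

test_that("MC error decays like one over the square root of N", {
  set.seed(14)
  slopes <- vapply(1:5, function(rep) {
    mod <- toy_model(8, seed = 140 + rep)
    p <- setNames(runif(8, 0.2, 0.8), mod$feature_ids)
    exact <- brute_force_expectation(mod, p)
    Ns <- c(100, 1000, 10000)
    rmse <- vapply(Ns, function(N) {
      errs <- vapply(1:12, function(s)
        predict_monte_carlo(mod, p, N = N, seed = 1000 * rep + s)$mean_score - exact,
        numeric(1))
      sqrt(mean(errs^2))
    }, numeric(1))
    unname(coef(lm(log(rmse) ~ log(Ns)))[2])
  }, numeric(1))
  expect_gt(mean(slopes), -0.6)
  expect_lt(mean(slopes), -0.4)
})

test_that("the enumeration oracle refuses oversized inputs and handles forced bits", {
  mod <- toy_model(25, seed = 15)
  p <- setNames(runif(25), mod$feature_ids)
  expect_error(brute_force_expectation(mod, p), "2\\^25")
  # only 3 free features: the rest forced
  p[4:25] <- rep(c(0, 1), length.out = 22)
  expect_silent(v <- brute_force_expectation(mod, p))
  mc <- predict_monte_carlo(mod, p, N = 20000, seed = 16)
  expect_lt(abs(mc$mean_score - v), 3 * mc$se + 1e-12)
  # d = 1 closed form
  m1 <- linear_scorer(c(f1 = 2), -1)
  expect_equal(unname(brute_force_expectation(m1, c(f1 = 0.3))),
               0.3 * plogis(1) + 0.7 * plogis(-1))
})

test_that("naive baseline uses the >= threshold convention", {
  mod <- toy_model(4, seed = 17)
  p <- setNames(c(0.5, 0.49, 0, 1), mod$feature_ids)
  nv <- predict_naive(mod, p)
  x <- matrix(c(1L, 0L, 0L, 1L), 1, dimnames = list(NULL, mod$feature_ids))
  expect_equal(unname(nv$score), unname(predict_scores(mod, x)))
  # threshold 0 makes everything present
  nv0 <- predict_naive(mod, p, feature_threshold = 0)
  x1 <- matrix(1L, 1, 4, dimnames = list(NULL, mod$feature_ids))
  expect_equal(unname(nv0$score), unname(predict_scores(mod, x1)))
})

test_that("convergence analysis flags borderline chemicals, not decisive ones", {
  mod <- toy_model(8, seed = 18)
  set.seed(19)
  # decisive chemical: expectation far from the class threshold
  repeat {
    p_far <- setNames(runif(8), mod$feature_ids)
    if (abs(brute_force_expectation(mod, p_far) - 0.5) > 0.2) break
  }
  conv <- convergence_analysis(mod, p_far, N_grid = c(100, 1000, 10000), seed = 20)
  expect_false(conv$flipped)
  # degenerate chemical never flips
  p_deg <- setNames(round(runif(8)), mod$feature_ids)
  expect_false(convergence_analysis(mod, p_deg, N_grid = c(100, 1000), seed = 21)$flipped)
  # borderline chemicals (expectation within 0.01 of the threshold) flip at
  # small N for at least one seed
  p_border <- setNames(rep(0.5, 8), mod$feature_ids)
  # tune the intercept (monotone in the expectation) until the true
  # expectation sits exactly at the class threshold
  g <- function(b) brute_force_expectation(
    linear_scorer(mod$weights, b), p_border) - 0.5
  b0 <- uniroot(g, c(-20, 20))$root
  border_mod <- linear_scorer(mod$weights, b0)
  flips <- vapply(1:20, function(s)
    convergence_analysis(border_mod, p_border, N_grid = c(10, 100, 10000),
                         seed = s)$flipped, logical(1))
  expect_gt(sum(flips), 0)
})

test_that("multi-output models are scored on the same sample stream per assay", {
  fp <- generate_fingerprints(150, 10, seed = 22)
  pm <- plant_toxicophores(fp, 2, 3, 2, target_prevalence = 0.2, seed = 22)
  lab <- simulate_labels(fp, pm, seed = 22)
  net <- train_multi_output(fp, lab, hidden = c(8), epochs = 10, seed = 23)
  p <- setNames(runif(10), colnames(fp))
  mc <- predict_monte_carlo(net, p, N = 300, seed = 24)
  expect_length(mc$mean_score, 2)
  expect_identical(colnames(mc$checkpoints), colnames(lab))
  expect_true(all(mc$mean_score >= 0 & mc$mean_score <= 1))
})
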