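# Synthetic data with the statistical structure of multi-assay toxicity
# screening panels: correlated binary fingerprint features, sparse planted
# toxicophores driving assay activity, missing labels, conflicting duplicate
# records, and noisy posterior-probability fingerprints.

#' Generate correlated binary fingerprint features
#'
#' Draws a chemicals x features presence/absence matrix from a latent-Gaussian
#' (copula) threshold model. Features are grouped into `n_blocks` contiguous
#' blocks; features within a block share pairwise latent correlation `rho`,
#' features across blocks are independent. The marginal prevalence of each
#' feature is drawn uniformly from `prevalence_range`, emulating the skewed
#' prevalence profile of structural-pattern fingerprints and producing the
#' correlated columns that motivate downstream correlation filtering.
#'
#' @param n_chem Number of chemicals (rows), at least 2.
#' @param d Number of fingerprint features (columns).
#' @param n_blocks Number of correlated feature blocks, `1 <= n_blocks <= d`.
#' @param rho Latent pairwise correlation within a block, in `[0, 1)`.
#' @param prevalence_range Interval within (0, 1) from which per-feature
#'   marginal prevalences are drawn.
#' @param seed Integer seed; identical inputs and seed give identical tables.
#' @return Integer matrix of 0/1 bits with `chem_id` rownames and
#'   `feature_id` colnames.
#' @export
#' @examples
#' fp <- generate_fingerprints(100, 20, n_blocks = 4, rho = 0.6, seed = 1)
#' colMeans(fp)
generate_fingerprints <- function(n_chem, d, n_blocks = 1, rho = 0,
                                  prevalence_range = c(0.05, 0.5), seed = 1) {
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho >= 1)
    stop("rho must lie in [0, 1)", call. = FALSE)
  stopifnot(n_chem >= 2, d >= n_blocks, n_blocks >= 1)
  stopifnot(length(prevalence_range) == 2,
            prevalence_range[1] > 0, prevalence_range[2] < 1,
            prevalence_range[1] <= prevalence_range[2])
  set.seed(child_seed(seed, "generate_fingerprints"))
  prev <- runif(d, prevalence_range[1], prevalence_range[2])
  block <- sort(rep_len(seq_len(n_blocks), d))
  b <- matrix(rnorm(n_chem * n_blocks), n_chem, n_blocks)
  z <- sqrt(rho) * b[, block, drop = FALSE] +
    sqrt(1 - rho) * matrix(rnorm(n_chem * d), n_chem, d)
  bits <- matrix(0L, n_chem, d,
                 dimnames = list(make_ids("chem", n_chem), make_ids("fp", d)))
  bits[z <= matrix(qnorm(prev), n_chem, d, byrow = TRUE)] <- 1L
  attr(bits, "prevalence") <- stats::setNames(prev, colnames(bits))
  attr(bits, "block") <- stats::setNames(block, colnames(bits))
  bits
}

#' Plant sparse toxicophores behind a panel of assays
#'
#' Builds the ground-truth model used by [simulate_labels()]: for each assay a
#' sparse logistic weight vector with exactly `sparsity` nonzero weights of
#' magnitude `effect_size`, where a `share_fraction` of the causal features is
#' drawn from a pool shared by all assays (inducing inter-assay label
#' correlation, as seen between biologically related bioassays). Each assay's
#' intercept is calibrated by bisection so the mean activation probability
#' over the supplied fingerprints matches `target_prevalence` within 0.002.
#'
#' @param fingerprints Binary fingerprint table from [generate_fingerprints()].
#' @param n_assays Number of assays.
#' @param sparsity Number of causal features per assay.
#' @param effect_size Magnitude of nonzero weights (positive).
#' @param share_fraction Fraction of each assay's causal features taken from
#'   the shared pool, in `[0, 1]`.
#' @param target_prevalence Per-assay active prevalence in (0, 1); recycled.
#' @param random_sign If `TRUE`, nonzero weights get random signs; default all
#'   positive.
#' @param seed Integer seed.
#' @return A `planted_model`: list with `weights` (features x assays matrix),
#'   `intercepts`, `shared_feature_ids`, `target_prevalence`.
#' @export
plant_toxicophores <- function(fingerprints, n_assays, sparsity, effect_size,
                               share_fraction = 0, target_prevalence = 0.05,
                               random_sign = FALSE, seed = 1) {
  validate_bits(fingerprints)
  feature_ids <- colnames(fingerprints)
  d <- length(feature_ids)
  stopifnot(sparsity <= d, n_assays >= 1,
            share_fraction >= 0, share_fraction <= 1, effect_size >= 0)
  target_prevalence <- rep_len(target_prevalence, n_assays)
  stopifnot(all(target_prevalence > 0), all(target_prevalence < 1))
  set.seed(child_seed(seed, "plant_toxicophores"))
  assay_ids <- make_ids("assay", n_assays)
  n_shared <- as.integer(round_half_away(share_fraction * sparsity))
  shared <- sample(feature_ids, n_shared)
  w <- matrix(0, d, n_assays, dimnames = list(feature_ids, assay_ids))
  for (a in seq_len(n_assays)) {
    own <- sample(setdiff(feature_ids, shared), sparsity - n_shared)
    causal <- c(shared, own)
    sgn <- if (random_sign) sample(c(-1, 1), sparsity, replace = TRUE) else 1
    w[causal, a] <- sgn * effect_size
  }
  eta0 <- fingerprints %*% w
  intercepts <- vapply(seq_len(n_assays), function(a) {
    f <- function(b) mean(sigmoid(eta0[, a] + b)) - target_prevalence[a]
    lo <- -50; hi <- 50
    if (f(lo) > 0 || f(hi) < 0)
      stop(sprintf("intercept bisection cannot bracket target prevalence for %s",
                   assay_ids[a]), call. = FALSE)
    stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
  }, numeric(1))
  names(intercepts) <- assay_ids
  # calibration contract: achieved prevalence within 0.002 of target
  achieved <- colMeans(sigmoid(sweep(eta0, 2, intercepts, `+`)))
  stopifnot(all(abs(achieved - target_prevalence) <= 0.002))
  structure(list(weights = w, intercepts = intercepts,
                 shared_feature_ids = shared,
                 target_prevalence = stats::setNames(target_prevalence, assay_ids)),
            class = "planted_model")
}

#' @export
print.planted_model <- function(x, ...) {
  cat(sprintf("Planted toxicophore model: %d assays, %d features (%d causal per assay, %d shared)\n",
              ncol(x$weights), nrow(x$weights),
              sum(x$weights[, 1] != 0), length(x$shared_feature_ids)))
  cat("target prevalence:", paste(sprintf("%.3f", x$target_prevalence), collapse = " "), "\n")
  invisible(x)
}

#' Simulate a sparse multi-assay label matrix from a planted model
#'
#' Labels are drawn `y ~ Bernoulli(sigmoid(w_a . x + b_a))` independently per
#' assay, then set missing completely at random at `missing_rate` per assay
#' (the three-value active/inactive/inconclusive coding of screening panels).
#'
#' @param fingerprints Binary fingerprint table; must contain the model's
#'   features.
#' @param model A `planted_model` from [plant_toxicophores()].
#' @param missing_rate Per-assay missingness probability in `[0, 1)`; recycled.
#' @param seed Integer seed.
#' @return Integer matrix chemicals x assays over `{1, 0, NA}`.
#' @export
simulate_labels <- function(fingerprints, model, missing_rate = 0, seed = 1) {
  validate_bits(fingerprints)
  stopifnot(inherits(model, "planted_model"))
  feats <- rownames(model$weights)
  if (!all(feats %in% colnames(fingerprints)))
    stop("fingerprint table lacks model features: ",
         paste(head(setdiff(feats, colnames(fingerprints))), collapse = ", "))
  n_assays <- ncol(model$weights)
  missing_rate <- rep_len(missing_rate, n_assays)
  stopifnot(all(missing_rate >= 0), all(missing_rate < 1))
  set.seed(child_seed(seed, "simulate_labels"))
  eta <- sweep(fingerprints[, feats, drop = FALSE] %*% model$weights,
               2, model$intercepts, `+`)
  n <- nrow(eta)
  y <- matrix(rbinom(length(eta), 1L, sigmoid(eta)), n, n_assays,
              dimnames = list(rownames(fingerprints), colnames(model$weights)))
  miss <- matrix(runif(length(eta)), n, n_assays) <
    matrix(missing_rate, n, n_assays, byrow = TRUE)
  y[miss] <- NA_integer_
  y
}

#' Emit raw records with conflicting duplicate entries
#'
#' Re-emits a fraction of chemicals as 2 or 3 records to emulate screening
#' collections where the same chemical appears multiple times with occasionally
#' conflicting experimental results. The first record of each chemical keeps
#' its original labels; each additional copy has its non-missing labels
#' independently flipped with probability `flip_prob`, so deduplication can be
#' verified against the intact ground truth.
#'
#' @param labels Label matrix over `{1, 0, NA}`.
#' @param dup_fraction Fraction of chemicals emitted more than once.
#' @param flip_prob Per-label flip probability for the extra copies.
#' @param copies Total emissions per duplicated chemical: 2, 3, or `"random"`
#'   (uniform over 2:3 per chemical).
#' @param seed Integer seed.
#' @return A data.frame of raw records: `chem_id` column plus one column per
#'   assay, possibly several rows per `chem_id` (a `RawRecordSet`).
#' @export
inject_duplicates <- function(labels, dup_fraction = 0, flip_prob = 0,
                              copies = 2, seed = 1) {
  validate_labels(labels)
  stopifnot(dup_fraction >= 0, dup_fraction <= 1, flip_prob >= 0, flip_prob <= 1)
  set.seed(child_seed(seed, "inject_duplicates"))
  n <- nrow(labels)
  ids <- rownames(labels)
  n_dup <- as.integer(round_half_away(dup_fraction * n))
  dup_ids <- if (n_dup > 0) sample(ids, n_dup) else character(0)
  n_copies <- if (identical(copies, "random")) {
    sample(2:3, n_dup, replace = TRUE)
  } else {
    stopifnot(copies %in% 2:3); rep_len(as.integer(copies), n_dup)
  }
  extra <- rep(dup_ids, times = pmax(n_copies - 1L, 0L))
  rec <- labels[c(ids, extra), , drop = FALSE]
  if (length(extra) > 0) {
    block <- rec[(n + 1):nrow(rec), , drop = FALSE]
    flip <- matrix(runif(length(block)) < flip_prob, nrow(block), ncol(block))
    flip[is.na(block)] <- FALSE
    block[flip] <- 1L - block[flip]
    rec[(n + 1):nrow(rec), ] <- block
  }
  out <- data.frame(chem_id = c(ids, extra), rec, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out
}

#' Specify per-feature fingerprint-prediction reliability
#'
#' Describes how faithfully a posterior-probability fingerprint predictor
#' recovers each true bit: feature `j` is mispredicted (at the 0.5 threshold)
#' with probability `e_j`. Most features get a small error drawn from
#' `error_range`; a `hard_fraction` of features are "hard" with elevated error
#' `hard_error`, giving the heavy tail of unreliable structural patterns seen
#' in practice. `shape` gives the Beta concentration of the emitted posterior
#' around the (possibly flipped) bit; `shape = c(Inf, Inf)` is the degenerate
#' noiseless mode that emits the bit itself.
#'
#' @param feature_ids Character vector of feature names.
#' @param error_range Interval for baseline per-feature error rates.
#' @param hard_fraction Fraction of features with elevated error.
#' @param hard_error Error rate of hard features.
#' @param shape Beta shape pair `(a, b)` of the concordant distribution for a
#'   true 1 (mirrored for a true 0).
#' @param seed Integer seed.
#' @return A `reliability_spec` object.
#' @export
reliability_spec <- function(feature_ids, error_range = c(0.02, 0.04),
                             hard_fraction = 0.05, hard_error = 0.12,
                             shape = c(8, 2), seed = 1) {
  stopifnot(length(error_range) == 2, error_range[1] <= error_range[2],
            hard_fraction >= 0, hard_fraction <= 1)
  if (any(c(error_range, hard_error) < 0) || any(c(error_range, hard_error) > 1))
    stop("error rates must lie in [0, 1]", call. = FALSE)
  set.seed(child_seed(seed, "reliability_spec"))
  d <- length(feature_ids)
  e <- runif(d, error_range[1], error_range[2])
  n_hard <- as.integer(round_half_away(hard_fraction * d))
  if (n_hard > 0) e[sample.int(d, n_hard)] <- hard_error
  structure(list(error = stats::setNames(e, feature_ids),
                 shape1 = shape[1], shape2 = shape[2]),
            class = "reliability_spec")
}

#' @export
print.reliability_spec <- function(x, ...) {
  cat(sprintf("Reliability spec: %d features, mean error %.3f (max %.3f), Beta(%s, %s) posteriors\n",
              length(x$error), mean(x$error), max(x$error),
              format(x$shape1), format(x$shape2)))
  invisible(x)
}

#' Emulate posterior-probability fingerprints from true bits
#'
#' Produces the probabilistic analogue of a binary fingerprint table: for each
#' entry a posterior probability concentrated near the true bit (concordant
#' Beta draw) or near its complement (discordant draw). The discordant mixture
#' weight is calibrated internally so that thresholding the emitted
#' probability at 0.5 mispredicts the true bit with probability exactly
#' `e_j` per feature, accounting for the Beta tail mass that crosses 0.5
#' (`pbeta(0.5, shape1, shape2)`). Features whose configured error is below
#' that floor are clamped to it with a warning.
#'
#' @param bits Binary fingerprint table (the ground truth).
#' @param spec A [reliability_spec()] covering all features of `bits`.
#' @param seed Integer seed.
#' @return Numeric matrix of probabilities in `[0, 1]`, same shape and
#'   dimnames as `bits`.
#' @export
emulate_probabilistic_fingerprints <- function(bits, spec, seed = 1) {
  validate_bits(bits)
  stopifnot(inherits(spec, "reliability_spec"))
  if (!all(colnames(bits) %in% names(spec$error)))
    stop("reliability spec does not cover features: ",
         paste(head(setdiff(colnames(bits), names(spec$error))), collapse = ", "))
  e <- spec$error[colnames(bits)]
  check_prob(e, "per-feature error rates")
  set.seed(child_seed(seed, "emulate_probabilistic_fingerprints"))
  n <- nrow(bits); d <- ncol(bits)
  if (!is.finite(spec$shape1) || !is.finite(spec$shape2)) {
    # degenerate noiseless mode: the posterior is the bit itself
    if (any(e > 0)) stop("infinite concentration requires zero error rates")
    probs <- bits + 0
    return(probs)
  }
  leak <- pbeta(0.5, spec$shape1, spec$shape2)
  if (any(e < leak)) {
    warning(sprintf(
      "error rates below the Beta(%.3g, %.3g) threshold-leak floor %.4f were clamped",
      spec$shape1, spec$shape2, leak))
    e <- pmax(e, leak)
  }
  w_disc <- (e - leak) / (1 - 2 * leak)
  emat <- matrix(w_disc, n, d, byrow = TRUE)
  discordant <- matrix(runif(n * d), n, d) < emat
  eff <- bits
  eff[discordant] <- 1L - eff[discordant]
  draw <- matrix(rbeta(n * d, spec$shape1, spec$shape2), n, d)
  probs <- ifelse(eff == 1L, draw, 1 - draw)
  dimnames(probs) <- dimnames(bits)
  probs
}
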