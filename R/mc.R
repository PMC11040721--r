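# Monte Carlo consumption of probabilistic fingerprints by binary-trained
# models: Bernoulli sampling of feature vectors, score averaging, an exact
# enumeration oracle, the fixed-threshold baseline, and convergence analysis.

# samples are produced in fixed-size blocks with per-block child seeds, so the
# first N rows are identical regardless of the total number requested
MC_BLOCK <- 512L

mc_sample_block <- function(p, block, seed) {
  set.seed(child_seed(seed, paste0("mc_block_", block)))
  d <- length(p)
  m <- matrix(runif(MC_BLOCK * d), MC_BLOCK, d)
  out <- matrix(0L, MC_BLOCK, d, dimnames = list(NULL, names(p)))
  out[m < matrix(p, MC_BLOCK, d, byrow = TRUE)] <- 1L
  out
}

#' Sample binary fingerprint vectors from per-feature probabilities
#'
#' Draws `N` vectors with entries independently `Bernoulli(p_j)` across
#' samples and features. Sampling is blocked with per-block child seeds, so
#' for a fixed seed the first `N'` rows of a larger draw equal a fresh draw
#' of `N'` rows (prefix consistency).
#'
#' @param p Probability vector in `[0, 1]` (named by feature).
#' @param N Number of vectors.
#' @param seed Integer seed.
#' @return Integer matrix `N x length(p)` of 0/1 entries.
#' @export
sample_binary_vectors <- function(p, N, seed = 1) {
  check_prob(p, "feature probabilities")
  stopifnot(N >= 1)
  n_blocks <- ceiling(N / MC_BLOCK)
  out <- do.call(rbind, lapply(seq_len(n_blocks), function(b)
    mc_sample_block(p, b, seed)))
  out[seq_len(N), , drop = FALSE]
}

#' Monte Carlo prediction from a probabilistic fingerprint
#'
#' Draws `N` binary fingerprint vectors from `Bernoulli(p_j)`, scores each
#' with the binary-trained model, and averages the `N` scores into the final
#' prediction (the estimator of the expected score under the posterior).
#' Running means are checkpointed on a sub-grid of `N` with common random
#' numbers (prefix reuse), so convergence curves are coherent across
#' checkpoints. Multi-output models are scored on the same `N` samples,
#' returning one mean score per assay.
#'
#' @param model Any model honouring the [predict_scores()] contract.
#' @param p Named probability vector covering the model's `feature_ids`;
#'   extra entries are ignored. Only the features the model consumes are
#'   sampled.
#' @param N Number of Monte Carlo samples (default 10000).
#' @param class_threshold Final-class rule: active iff
#'   `mean_score >= class_threshold` (default 0.5).
#' @param checkpoints Increasing sample counts at which running means are
#'   recorded; defaults to powers of 10 up to `N`.
#' @param seed Integer seed.
#' @param chem_id Optional identifier carried into the result.
#' @return An `mc_prediction`: `mean_score`, `se` (Monte Carlo standard
#'   error), `final_class`, `N`, `checkpoints` (running means), and for
#'   multi-output models one column per assay.
#' @export
predict_monte_carlo <- function(model, p, N = 10000, class_threshold = 0.5,
                                checkpoints = NULL, seed = 1, chem_id = NA_character_) {
  feats <- model$feature_ids
  if (is.null(names(p)) && length(p) == length(feats)) names(p) <- feats
  miss <- setdiff(feats, names(p))
  if (length(miss) > 0)
    stop("probability vector lacks model features: ",
         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  p <- p[feats]
  check_prob(p, "feature probabilities")
  checkpoints <- sort(unique(c(checkpoints %||% 10^(1:floor(log10(N))), N)))
  checkpoints <- checkpoints[checkpoints <= N]
  n_blocks <- ceiling(N / MC_BLOCK)
  run_sum <- NULL; run_sq <- NULL; done <- 0L
  cp_means <- NULL
  for (b in seq_len(n_blocks)) {
    xb <- mc_sample_block(p, b, seed)
    take <- min(MC_BLOCK, N - done)
    xb <- xb[seq_len(take), , drop = FALSE]
    sc <- predict_scores(model, xb)
    sc <- as.matrix(sc)                      # N x 1 or N x assays
    if (is.null(run_sum)) {
      run_sum <- rep(0, ncol(sc)); run_sq <- rep(0, ncol(sc))
      cp_means <- matrix(NA_real_, length(checkpoints), ncol(sc),
                         dimnames = list(checkpoints, colnames(sc)))
    }
    # record running means at checkpoints interior to this block
    cs <- apply(sc, 2, cumsum)
    cs <- matrix(cs, nrow = take)
    inside <- which(checkpoints > done & checkpoints <= done + take)
    for (k in inside)
      cp_means[k, ] <- (run_sum + cs[checkpoints[k] - done, ]) / checkpoints[k]
    run_sum <- run_sum + cs[take, ]
    run_sq <- run_sq + colSums(sc^2)
    done <- done + take
  }
  mean_score <- run_sum / N
  v <- pmax(run_sq / N - mean_score^2, 0)
  structure(list(chem_id = chem_id,
                 mean_score = mean_score,
                 se = sqrt(v / N),
                 N = N,
                 class_threshold = class_threshold,
                 final_class = as.integer(mean_score >= class_threshold),
                 checkpoints = cp_means),
            class = "mc_prediction")
}

#' @export
print.mc_prediction <- function(x, ...) {
  cat(sprintf("Monte Carlo prediction (N = %d%s)\n", x$N,
              if (!is.na(x$chem_id)) paste0(", chem ", x$chem_id) else ""))
  out <- data.frame(mean_score = round(x$mean_score, 4),
                    se = signif(x$se, 3), class = x$final_class)
  print(out)
  invisible(x)
}

#' Exact expectation of the Monte Carlo estimand
#'
#' Enumerates all completions of the features with `0 < p_j < 1` (the others
#' are forced) and returns the probability-weighted mean score — the exact
#' quantity the Monte Carlo average estimates. Exponential in the number of
#' free features, hence restricted to small models.
#'
#' @inheritParams predict_monte_carlo
#' @param max_free Maximum number of free features (default 20).
#' @return Exact expected score (vector with one entry per assay for
#'   multi-output models).
#' @export
brute_force_expectation <- function(model, p, max_free = 20) {
  feats <- model$feature_ids
  if (is.null(names(p)) && length(p) == length(feats)) names(p) <- feats
  p <- p[feats]
  check_prob(p, "feature probabilities")
  free <- which(p > 0 & p < 1)
  f <- length(free)
  if (f > max_free)
    stop(sprintf(paste("%d free features would require 2^%d enumerations;",
                       "use predict_monte_carlo for larger models"), f, f),
         call. = FALSE)
  base <- as.integer(p >= 1)
  if (f == 0) {
    x <- matrix(base, 1, dimnames = list(NULL, feats))
    return(drop(as.matrix(predict_scores(model, x))[1, ]))
  }
  combos <- as.matrix(expand.grid(rep(list(0:1), f)))
  x <- matrix(rep(base, each = nrow(combos)), nrow(combos), length(feats),
              dimnames = list(NULL, feats))
  x[, free] <- combos
  pf <- p[free]
  logw <- combos %*% log(pf) + (1 - combos) %*% log(1 - pf)
  w <- exp(as.numeric(logw))
  sc <- as.matrix(predict_scores(model, x))
  drop(crossprod(sc, w))
}

#' Fixed-threshold (naive) baseline prediction
#'
#' Binarizes the probabilistic fingerprint at `feature_threshold` (with
#' `p >= threshold` counted as present) and scores the model once.
#'
#' @inheritParams predict_monte_carlo
#' @param feature_threshold Binarization threshold (default 0.5).
#' @return List with `score` and `class` (per assay for multi-output models).
#' @export
predict_naive <- function(model, p, feature_threshold = 0.5,
                          class_threshold = 0.5) {
  feats <- model$feature_ids
  if (is.null(names(p)) && length(p) == length(feats)) names(p) <- feats
  p <- p[feats]
  check_prob(p, "feature probabilities")
  x <- matrix(as.integer(p >= feature_threshold), 1,
              dimnames = list(NULL, feats))
  sc <- drop(as.matrix(predict_scores(model, x))[1, ])
  list(score = sc, class = as.integer(sc >= class_threshold))
}

#' Convergence of Monte Carlo predictions over the sample-size grid
#'
#' For each chemical, the thresholded class is tracked at every checkpoint of
#' `N_grid` (using nested sample reuse, so checkpoints are consistent
#' prefixes of one stream). A chemical is flagged when its class at any
#' smaller `N` differs from the class at `max(N_grid)` — the chemicals for
#' which inadequate sampling would flip the activity call.
#'
#' @param model Model honouring the scoring contract.
#' @param probs Probabilistic fingerprint table (chemicals x features) or a
#'   single named probability vector.
#' @param N_grid Increasing vector of sample counts.
#' @param class_threshold Class threshold (default 0.5).
#' @param seed Integer seed; each chemical gets a child seed.
#' @return data.frame with per chemical (and per assay for multi-output
#'   models): mean score at max N, class per checkpoint, and a `flipped`
#'   flag.
#' @export
convergence_analysis <- function(model, probs, N_grid = c(100, 1000, 10000),
                                 class_threshold = 0.5, seed = 1) {
  stopifnot(!is.unsorted(N_grid), length(N_grid) >= 2)
  if (is.null(dim(probs))) probs <- matrix(probs, 1, dimnames = list(
    "chem_0001", names(probs)))
  Nmax <- max(N_grid)
  out <- vector("list", nrow(probs))
  for (i in seq_len(nrow(probs))) {
    mc <- predict_monte_carlo(model, probs[i, ], N = Nmax,
                              class_threshold = class_threshold,
                              checkpoints = N_grid,
                              seed = child_seed(seed, paste0("conv_", i)))
    cls <- mc$checkpoints >= class_threshold
    final <- cls[nrow(cls), , drop = TRUE]
    flipped <- apply(cls, 2, function(col) any(col != col[length(col)]))
    out[[i]] <- data.frame(chem_id = rownames(probs)[i],
                           assay = colnames(mc$checkpoints) %||% "score",
                           mean_score = as.numeric(mc$mean_score),
                           final_class = as.integer(final),
                           flipped = as.logical(flipped),
                           row.names = NULL)
  }
  do.call(rbind, out)
}
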