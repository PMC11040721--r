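# Single-output classifiers with grid-search CV, and the uniform scoring
# contract shared by all model types.

#' Train a single-assay classifier by grid-search cross-validation
#'
#' For each hyperparameter grid point, the mean out-of-fold ROC-AUC over the
#' supplied folds is computed; the model is then refit on the full training
#' data at the best grid point (ties resolve to the first grid point in
#' order). Rows with a missing label for this assay are dropped before
#' training. Optional imbalance resampling is applied inside each CV fold
#' (and to the full data at refit), never to held-out rows.
#'
#' @param x Numeric feature matrix (chemicals x features) with colnames.
#' @param y Labels for one assay: 0/1 with `NA` for missing.
#' @param algorithm `"logistic"` (stats::glm), `"random_forest"` (ranger
#'   probability forest; score = fraction of trees voting active) or
#'   `"gradient_boosting"` (xgboost, logistic objective).
#' @param grid List of named hyperparameter lists; `NULL` uses a small
#'   per-algorithm default grid. An empty grid is an error.
#' @param folds Integer fold index per row of `x` (e.g. from
#'   [make_cv_folds()]); `NULL` fits without CV at the first grid point.
#' @param resample `"none"`, `"down"`, `"up"` or `"smote"`.
#' @param k_neighbors SMOTE neighbour count.
#' @param seed Integer seed.
#' @return A `fingertox_model` with `print`, `summary` and `predict` methods;
#'   `predict` returns activity scores in `[0, 1]`.
#' @export
train_single_output <- function(x, y, algorithm = c("logistic", "random_forest",
                                                    "gradient_boosting"),
                                grid = NULL, folds = NULL,
                                resample = c("none", "down", "up", "smote"),
                                k_neighbors = 5, seed = 1) {
  algorithm <- match.arg(algorithm)
  resample <- match.arg(resample)
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  if (is.null(colnames(x))) colnames(x) <- make_ids("fp", ncol(x))
  grid <- grid %||% default_grid(algorithm)
  if (length(grid) == 0) stop("hyperparameter grid must not be empty", call. = FALSE)
  obs <- !is.na(y)
  x <- x[obs, , drop = FALSE]; y <- as.numeric(y[obs])
  if (!is.null(folds)) folds <- folds[obs]
  if (length(unique(y)) < 2) stop("training labels contain a single class", call. = FALSE)

  cv <- NULL
  best_idx <- 1L
  if (!is.null(folds) && length(grid) >= 1) {
    fold_ids <- sort(unique(folds))
    auc <- matrix(NA_real_, length(grid), length(fold_ids))
    for (gi in seq_along(grid)) {
      for (fi in seq_along(fold_ids)) {
        hold <- folds == fold_ids[fi]
        ytr <- y[!hold]
        if (length(unique(ytr)) < 2 || length(unique(y[hold])) < 2) next
        fit <- fit_one(x[!hold, , drop = FALSE], ytr, algorithm, grid[[gi]],
                       resample, k_neighbors,
                       child_seed(seed, sprintf("cv_%d_%d", gi, fi)))
        sc <- score_fit(fit, algorithm, x[hold, , drop = FALSE])
        auc[gi, fi] <- roc_auc(sc, y[hold])
      }
    }
    mean_auc <- rowMeans(auc, na.rm = TRUE)
    mean_auc[is.nan(mean_auc)] <- NA_real_
    if (all(is.na(mean_auc))) {
      warning("no fold produced a valid ROC-AUC; using the first grid point")
    } else {
      best_idx <- which.max(mean_auc)   # ties -> first in grid order
    }
    cv <- data.frame(grid_point = seq_along(grid),
                     mean_roc_auc = mean_auc,
                     n_folds = rowSums(!is.na(auc)))
  }
  fit <- fit_one(x, y, algorithm, grid[[best_idx]], resample, k_neighbors,
                 child_seed(seed, "refit"))
  structure(list(algorithm = algorithm, fit = fit,
                 feature_ids = colnames(x),
                 hyperparameters = grid[[best_idx]],
                 grid = grid, best_index = best_idx, cv = cv,
                 resample = resample, n_train = nrow(x), seed = seed),
            class = "fingertox_model")
}

default_grid <- function(algorithm) {
  switch(algorithm,
    logistic = list(list()),
    random_forest = list(list(num.trees = 300, mtry = NULL),
                         list(num.trees = 300, mtry_frac = 0.25)),
    gradient_boosting = list(list(nrounds = 100, max_depth = 3, eta = 0.1),
                             list(nrounds = 100, max_depth = 6, eta = 0.1)))
}

fit_one <- function(x, y, algorithm, hp, resample, k_neighbors, seed) {
  if (resample != "none") {
    rb <- resample_balance(x, y, resample, k_neighbors, seed)
    x <- rb$x; y <- rb$y
  }
  switch(algorithm,
    logistic = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    random_forest = {
      mtry <- hp$mtry %||%
        if (!is.null(hp$mtry_frac)) max(1L, floor(hp$mtry_frac * ncol(x))) else NULL
      ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                     num.trees = hp$num.trees %||% 300,
                     mtry = mtry, probability = TRUE,
                     num.threads = 1, seed = seed)
    },
    gradient_boosting = {
      xgboost::xgboost(x, factor(y, levels = c(0, 1)),
                       nrounds = hp$nrounds %||% 100,
                       max_depth = hp$max_depth %||% 3,
                       learning_rate = hp$eta %||% 0.1,
                       nthreads = 1, seed = seed, verbosity = 0)
    })
}

score_fit <- function(fit, algorithm, x) {
  switch(algorithm,
    logistic = {
      df <- data.frame(x, check.names = FALSE)
      as.numeric(stats::predict(fit, newdata = df, type = "response"))
    },
    random_forest = {
      pr <- stats::predict(fit, data = x, num.threads = 1)$predictions
      as.numeric(pr[, "1"])
    },
    gradient_boosting = {
      pr <- stats::predict(fit, x, type = "response")
      if (is.matrix(pr)) as.numeric(pr[, "1"]) else as.numeric(pr)
    })
}

#' Score chemicals with a trained model
#'
#' Uniform scoring contract across model types: a pure function of the fitted
#' state and the input rows, preserving row order. The input must contain all
#' features the model consumes (matched by name; extra columns are ignored).
#'
#' @param model A `fingertox_model`, `fingertox_net` or `fingertox_linear`.
#' @param x Binary (or continuous, e.g. SMOTE/sampled) feature matrix.
#' @return Numeric scores in `[0, 1]`: a vector for single-output models, a
#'   chemicals x assays matrix for multi-output models.
#' @export
predict_scores <- function(model, x) UseMethod("predict_scores")

align_features <- function(x, feature_ids) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    if (ncol(x) != length(feature_ids))
      stop("unnamed input has wrong number of columns", call. = FALSE)
    colnames(x) <- feature_ids
  }
  miss <- setdiff(feature_ids, colnames(x))
  if (length(miss) > 0)
    stop("input lacks required feature columns: ",
         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  x[, feature_ids, drop = FALSE]
}

#' @export
predict_scores.fingertox_model <- function(model, x) {
  x <- align_features(x, model$feature_ids)
  sc <- score_fit(model$fit, model$algorithm, x)
  names(sc) <- rownames(x)
  pmin(pmax(sc, 0), 1)
}

#' @rdname predict_scores
#' @param object,newdata,... standard `predict` interface delegating to
#'   `predict_scores`.
#' @export
predict.fingertox_model <- function(object, newdata, ...) {
  predict_scores(object, newdata)
}

#' @export
print.fingertox_model <- function(x, ...) {
  cat(sprintf("Single-output %s classifier (%d features, %d training rows, resampling: %s)\n",
              x$algorithm, length(x$feature_ids), x$n_train, x$resample))
  if (!is.null(x$cv))
    cat(sprintf("selected grid point %d of %d (mean CV ROC-AUC %.3f)\n",
                x$best_index, length(x$grid), x$cv$mean_roc_auc[x$best_index]))
  invisible(x)
}

#' @export
summary.fingertox_model <- function(object, ...) {
  print(object)
  if (!is.null(object$cv)) {
    cat("\nCross-validation summary:\n")
    print(object$cv, row.names = FALSE)
  }
  invisible(object$cv)
}

#' A fixed linear-logistic scorer
#'
#' Wraps a weight vector and intercept as a model satisfying the scoring
#' contract: `score(x) = sigmoid(x . w + b)`. Used as a transparent reference
#' model (e.g. the planted ground truth) and in exact-expectation checks.
#'
#' @param weights Named numeric weight vector (names are feature ids).
#' @param intercept Scalar intercept.
#' @return A `fingertox_linear` model.
#' @export
linear_scorer <- function(weights, intercept = 0) {
  stopifnot(!is.null(names(weights)))
  structure(list(weights = weights, intercept = intercept,
                 feature_ids = names(weights)),
            class = "fingertox_linear")
}

#' @export
predict_scores.fingertox_linear <- function(model, x) {
  x <- align_features(x, model$feature_ids)
  sc <- sigmoid(as.numeric(x %*% model$weights) + model$intercept)
  names(sc) <- rownames(x)
  sc
}

#' @export
print.fingertox_linear <- function(x, ...) {
  cat(sprintf("Linear-logistic scorer over %d features (intercept %.3f)\n",
              length(x$weights), x$intercept))
  invisible(x)
}
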