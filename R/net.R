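# Multi-output network with missing-label-masked cross-entropy, implemented
# as plain matrix code: ReLU hidden layers, per-assay sigmoid outputs,
# optional batch normalization / dropout / L2, Adam optimizer, early stopping
# on a masked validation loss.

#' Masked mean binary cross-entropy
#'
#' `L = -(1/M) * sum over observed cells of [y log p + (1 - y) log(1 - p)]`,
#' where `M` is the number of observed (non-missing) label cells. Missing
#' cells contribute zero loss and have exactly zero gradient; with no missing
#' labels this equals the standard mean binary cross-entropy.
#'
#' @param predictions Numeric matrix (or vector) of probabilities in (0, 1);
#'   values are clipped to `[eps, 1 - eps]`.
#' @param labels Matching matrix over `{1, 0, NA}`.
#' @param eps Clipping constant.
#' @return Scalar loss; 0 with a warning when every label is missing.
#' @export
#' @examples
#' masked_bce(c(0.8, 0.2, 0.9), c(1, 0, NA))  # -(log .8 + log .8) / 2
masked_bce <- function(predictions, labels, eps = 1e-12) {
  p <- pmin(pmax(as.numeric(predictions), eps), 1 - eps)
  y <- as.numeric(labels)
  stopifnot(length(p) == length(y))
  obs <- !is.na(y)
  if (!any(obs)) {
    warning("all labels missing; masked loss defined as 0")
    return(0)
  }
  -mean(y[obs] * log(p[obs]) + (1 - y[obs]) * log(1 - p[obs]))
}

#' @describeIn masked_bce Gradient of the masked loss with respect to the
#'   predictions; exactly zero at missing cells.
#' @export
masked_bce_grad <- function(predictions, labels, eps = 1e-12) {
  p <- pmin(pmax(predictions, eps), 1 - eps)
  g <- array(0, dim = dim(as.matrix(predictions)))
  obs <- !is.na(labels)
  m <- sum(obs)
  if (m == 0) return(g)
  y <- labels
  g[obs] <- -(y[obs] / p[obs] - (1 - y[obs]) / (1 - p[obs])) / m
  g
}

relu <- function(x) (x > 0) * x

init_net <- function(sizes, batch_norm) {
  L <- length(sizes) - 1
  W <- b <- gamma <- beta <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
    if (batch_norm && l < L) {
      gamma[[l]] <- rep(1, sizes[l + 1])
      beta[[l]] <- rep(0, sizes[l + 1])
    }
  }
  list(W = W, b = b, gamma = gamma, beta = beta)
}

# forward pass; training mode uses batch statistics and dropout, inference
# mode uses running batch-norm statistics and no dropout
net_forward <- function(params, x, cfg, state, training = FALSE) {
  L <- length(params$W)
  cache <- list(h = vector("list", L + 1), z = vector("list", L),
                zn = vector("list", L), sdv = vector("list", L),
                drop = vector("list", L))
  h <- x
  cache$h[[1]] <- h
  for (l in seq_len(L)) {
    z <- sweep(h %*% params$W[[l]], 2, params$b[[l]], `+`)
    if (l < L) {
      if (cfg$batch_norm) {
        if (training) {
          mu <- colMeans(z)
          v <- colMeans(sweep(z, 2, mu)^2)
          state$bn_mu[[l]] <- 0.9 * state$bn_mu[[l]] + 0.1 * mu
          state$bn_var[[l]] <- 0.9 * state$bn_var[[l]] + 0.1 * v
        } else {
          mu <- state$bn_mu[[l]]; v <- state$bn_var[[l]]
        }
        sdv <- sqrt(v + 1e-5)
        zn <- sweep(sweep(z, 2, mu), 2, sdv, `/`)
        cache$zn[[l]] <- zn; cache$sdv[[l]] <- sdv
        z <- sweep(sweep(zn, 2, params$gamma[[l]], `*`), 2, params$beta[[l]], `+`)
      }
      cache$z[[l]] <- z
      h <- relu(z)
      if (training && cfg$dropout > 0) {
        mask <- (matrix(runif(length(h)), nrow(h)) >= cfg$dropout) / (1 - cfg$dropout)
        h <- h * mask
        cache$drop[[l]] <- mask
      }
    } else {
      cache$z[[l]] <- z
      h <- sigmoid(z)
    }
    cache$h[[l + 1]] <- h
  }
  list(out = h, cache = cache, state = state)
}

# backprop of masked BCE (+ L2); dout is dL/dz at the output layer
net_backward <- function(params, cfg, cache, dout) {
  L <- length(params$W)
  gW <- gb <- ggamma <- gbeta <- vector("list", L)
  delta <- dout
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(cache$h[[l]], delta) + cfg$l2 * params$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      dh <- delta %*% t(params$W[[l]])
      if (cfg$dropout > 0 && !is.null(cache$drop[[l - 1]]))
        dh <- dh * cache$drop[[l - 1]]
      dz2 <- dh * (cache$z[[l - 1]] > 0)
      if (cfg$batch_norm) {
        zn <- cache$zn[[l - 1]]; sdv <- cache$sdv[[l - 1]]
        m <- nrow(dz2)
        ggamma[[l - 1]] <- colSums(dz2 * zn)
        gbeta[[l - 1]] <- colSums(dz2)
        dzn <- sweep(dz2, 2, params$gamma[[l - 1]], `*`)
        delta <- sweep(
          dzn - matrix(colMeans(dzn), m, ncol(dzn), byrow = TRUE) -
            zn * matrix(colMeans(dzn * zn), m, ncol(dzn), byrow = TRUE),
          2, sdv, `/`)
      } else {
        delta <- dz2
      }
    }
  }
  list(W = gW, b = gb, gamma = ggamma, beta = gbeta)
}

adam_step <- function(opt, params, grads, lr, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (field in c("W", "b", "gamma", "beta")) {
    for (l in seq_along(params[[field]])) {
      g <- grads[[field]][[l]]
      if (is.null(g) || is.null(params[[field]][[l]])) next
      opt$m[[field]][[l]] <- b1 * opt$m[[field]][[l]] + (1 - b1) * g
      opt$v[[field]][[l]] <- b2 * opt$v[[field]][[l]] + (1 - b2) * g^2
      mhat <- opt$m[[field]][[l]] / (1 - b1^t)
      vhat <- opt$v[[field]][[l]] / (1 - b2^t)
      params[[field]][[l]] <- params[[field]][[l]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(opt = opt, params = params)
}

#' Train a multi-output network with a masked multi-label loss
#'
#' Fits a fully connected network (ReLU hidden layers, one sigmoid output per
#' assay) by minimizing [masked_bce()] with the Adam optimizer. Missing label
#' cells are excluded from the loss, so sparse multi-assay panels train
#' without imputation. A validation slice is carved from the training data by
#' anticlustering (keeping its label composition representative) and monitors
#' early stopping; assays with no observed validation label are automatically
#' excluded from that monitor by the mask. Deterministic for a fixed seed
#' under single-threaded execution.
#'
#' @param x Numeric feature matrix with colnames.
#' @param labels Chemicals x assays matrix over `{1, 0, NA}`; every assay
#'   needs at least one observed cell.
#' @param hidden Integer vector of hidden-layer widths (up to 4 layers).
#' @param dropout Dropout rate in `[0, 1)` on hidden activations.
#' @param l2 L2 penalty on weights.
#' @param batch_norm Apply batch normalization to hidden pre-activations.
#' @param epochs Maximum training epochs.
#' @param batch_size Mini-batch size (default `min(128, n)`).
#' @param learning_rate Adam learning rate.
#' @param patience Early-stopping patience in epochs (`Inf` disables).
#' @param val_fraction Fraction of rows held out for the early-stopping
#'   monitor (0 disables early stopping).
#' @param seed Integer seed.
#' @param verbose Print per-epoch losses.
#' @return A `fingertox_net` with `print` and `predict` methods; `predict`
#'   returns a chemicals x assays score matrix.
#' @export
train_multi_output <- function(x, labels, hidden = c(64, 64), dropout = 0,
                               l2 = 0, batch_norm = FALSE, epochs = 200,
                               batch_size = NULL, learning_rate = 1e-3,
                               patience = 10, val_fraction = 0.1, seed = 1,
                               verbose = FALSE) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  validate_labels(labels)
  stopifnot(nrow(x) == nrow(labels), length(hidden) >= 1, length(hidden) <= 4,
            dropout >= 0, dropout < 1, l2 >= 0)
  if (any(colSums(!is.na(labels)) == 0))
    stop("every assay needs at least one observed label", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- make_ids("fp", ncol(x))
  n <- nrow(x); A <- ncol(labels)
  set.seed(child_seed(seed, "train_multi_output"))
  cfg <- list(dropout = dropout, l2 = l2, batch_norm = batch_norm)

  val_idx <- integer(0)
  if (val_fraction > 0 && n >= 20) {
    Kv <- max(2L, as.integer(round(1 / val_fraction)))
    folds <- make_cv_folds(labels, K = Kv, seed = child_seed(seed, "net_val"),
                           max_sweeps = 5)
    val_idx <- which(folds == 1L)
  }
  tr_idx <- setdiff(seq_len(n), val_idx)

  sizes <- c(ncol(x), hidden, A)
  params <- init_net(sizes, batch_norm)
  zero_like <- function(p) lapply(p, function(e) if (is.null(e)) NULL else e * 0)
  opt <- list(m = lapply(params, zero_like), v = lapply(params, zero_like))
  state <- list(bn_mu = lapply(hidden, function(w) rep(0, w)),
                bn_var = lapply(hidden, function(w) rep(1, w)))
  batch_size <- batch_size %||% min(128L, length(tr_idx))
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  best_val <- Inf; best_params <- params; best_state <- state; wait <- 0L
  t_step <- 0L

  for (ep in seq_len(epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    ep_loss <- 0; ep_m <- 0
    for (bi in batches) {
      xb <- x[bi, , drop = FALSE]; yb <- labels[bi, , drop = FALSE]
      fw <- net_forward(params, xb, cfg, state, training = TRUE)
      state <- fw$state
      m_obs <- sum(!is.na(yb))
      if (m_obs == 0) next
      p <- fw$out
      loss <- masked_bce(p, yb)
      if (!is.finite(loss))
        stop(sprintf("training diverged at epoch %d (loss %s); reduce learning_rate",
                     ep, format(loss)), call. = FALSE)
      ep_loss <- ep_loss + loss * m_obs; ep_m <- ep_m + m_obs
      # gradient of masked BCE wrt output pre-activation: (p - y) * mask / M
      dout <- (p - ifelse(is.na(yb), p, yb)) / m_obs
      grads <- net_backward(params, cfg, fw$cache, dout)
      t_step <- t_step + 1L
      st <- adam_step(opt, params, grads, learning_rate, t_step)
      opt <- st$opt; params <- st$params
    }
    train_loss <- ep_loss / max(ep_m, 1)
    val_loss <- NA_real_
    if (length(val_idx) > 0) {
      pv <- net_forward(params, x[val_idx, , drop = FALSE], cfg, state)$out
      val_loss <- suppressWarnings(masked_bce(pv, labels[val_idx, , drop = FALSE]))
      if (val_loss < best_val - 1e-6) {
        best_val <- val_loss; best_params <- params; best_state <- state
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    log <- rbind(log, data.frame(epoch = ep, train_loss = train_loss,
                                 val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %s", ep, train_loss,
                      ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
    if (length(val_idx) > 0 && wait >= patience) break
  }
  if (length(val_idx) > 0) { params <- best_params; state <- best_state }
  structure(list(params = params, state = state, cfg = cfg, sizes = sizes,
                 feature_ids = colnames(x), assay_ids = colnames(labels),
                 log = log, seed = seed,
                 n_train = length(tr_idx), n_val = length(val_idx)),
            class = "fingertox_net")
}

#' @export
predict_scores.fingertox_net <- function(model, x) {
  x <- align_features(x, model$feature_ids)
  out <- net_forward(model$params, x, model$cfg, model$state)$out
  dimnames(out) <- list(rownames(x), model$assay_ids)
  out
}

#' @rdname predict_scores
#' @export
predict.fingertox_net <- function(object, newdata, ...) {
  predict_scores(object, newdata)
}

#' @export
print.fingertox_net <- function(x, ...) {
  cat(sprintf("Multi-output network: %s -> %d sigmoid outputs (%d epochs trained)\n",
              paste(x$sizes[-length(x$sizes)], collapse = "-"),
              x$sizes[length(x$sizes)], nrow(x$log)))
  cat(sprintf("masked training loss %.4f -> %.4f",
              x$log$train_loss[1], x$log$train_loss[nrow(x$log)]))
  if (x$n_val > 0)
    cat(sprintf("; best validation loss %.4f (n_val = %d)",
                min(x$log$val_loss, na.rm = TRUE), x$n_val))
  cat("\n")
  invisible(x)
}
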