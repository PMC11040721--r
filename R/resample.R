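# Class-imbalance resampling for single-assay training sets.

#' Rebalance a binary training set
#'
#' `down` subsamples the majority class without replacement to the minority
#' size; `up` resamples the minority class with replacement to the majority
#' size; `smote` adds synthetic minority points as convex combinations
#' `x_new = x_i + u * (x_nn - x_i)` with `u ~ Uniform(0, 1)` and `x_nn` one of
#' the `k_neighbors` nearest minority neighbours of `x_i` (Euclidean
#' distance). SMOTE outputs are left continuous in `[0, 1]`; tree ensembles
#' and networks consume them directly.
#'
#' @param x Numeric feature matrix.
#' @param y Binary 0/1 vector (no missing values).
#' @param method One of `"down"`, `"up"`, `"smote"`.
#' @param k_neighbors Number of minority neighbours for SMOTE (default 5;
#'   reduced with a warning when the minority class is too small).
#' @param seed Integer seed.
#' @return List with rebalanced `x` and `y`.
#' @export
resample_balance <- function(x, y, method = c("down", "up", "smote"),
                             k_neighbors = 5, seed = 1) {
  method <- match.arg(method)
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), !anyNA(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2)
    stop("both classes must be present for resampling", call. = FALSE)
  set.seed(child_seed(seed, paste0("resample_", method)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  minority <- if (n1 <= n0) 1 else 0
  idx_min <- which(y == minority); idx_maj <- which(y != minority)
  if (method == "down") {
    keep <- c(idx_min, sample(idx_maj, length(idx_min)))
    return(list(x = x[keep, , drop = FALSE], y = y[keep]))
  }
  if (method == "up") {
    extra <- sample(idx_min, length(idx_maj) - length(idx_min), replace = TRUE)
    keep <- c(idx_maj, idx_min, extra)
    return(list(x = x[keep, , drop = FALSE], y = y[keep]))
  }
  # smote
  n_syn <- length(idx_maj) - length(idx_min)
  if (n_syn <= 0) return(list(x = x, y = y))
  k <- k_neighbors
  if (length(idx_min) - 1 < k) {
    k <- max(1L, length(idx_min) - 1L)
    warning(sprintf("minority class too small for k_neighbors = %d; reduced to %d",
                    k_neighbors, k))
  }
  xm <- x[idx_min, , drop = FALSE]
  dd <- as.matrix(stats::dist(xm))
  diag(dd) <- Inf
  nn <- t(apply(dd, 1, function(r) order(r)[seq_len(k)]))
  base <- sample.int(nrow(xm), n_syn, replace = TRUE)
  pick <- nn[cbind(base, sample.int(k, n_syn, replace = TRUE))]
  u <- runif(n_syn)
  syn <- xm[base, , drop = FALSE] + u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  rownames(syn) <- sprintf("smote_%04d", seq_len(n_syn))
  list(x = rbind(x, syn), y = c(y, rep(minority, n_syn)))
}
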