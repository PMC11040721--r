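# Anticlustering-based partitioning: heterogeneous, mutually similar groups
# for train/test splits and CV folds, plus proportion-matched stratified
# subsetting.

#' Partition items into K maximally heterogeneous, mutually similar groups
#'
#' Balanced random initialization followed by a pairwise exchange local
#' search on the diversity objective: the sum over groups of within-group
#' pairwise squared Euclidean distances. A swap of two items in different
#' groups is applied whenever it increases the objective; the search stops at
#' a sweep with no improving swap or after `max_sweeps` sweeps. Group sizes
#' differ by at most one; when `n %% K != 0` the first `n %% K` groups (by
#' group index) receive the extra item. The squared-Euclidean diversity is
#' evaluated through the centroid identity
#' `sum_{i<j in g} ||x_i - x_j||^2 = n_g * sum_{i in g} ||x_i - c_g||^2`,
#' which makes each candidate swap O(d).
#'
#' @param x Numeric matrix (items x variables); rownames are item ids.
#' @param K Number of groups, `1 <= K <= n`.
#' @param max_sweeps Maximum number of full exchange sweeps (default 20).
#' @param restarts Number of random restarts; the assignment with the best
#'   objective is returned (default 1).
#' @param seed Integer seed.
#' @return An `anticlustering` object: list with `ids`, `groups` (integer in
#'   `1..K`), `K`, `objective_value`, `objective_initial`, `sweeps`.
#' @export
#' @examples
#' x <- matrix(rnorm(40), 20, 2)
#' ac <- anticluster(x, K = 4, seed = 1)
#' table(ac$groups)
anticluster <- function(x, K, max_sweeps = 20, restarts = 1, seed = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (K > n) stop("K must not exceed the number of items", call. = FALSE)
  stopifnot(K >= 1, max_sweeps >= 0, restarts >= 1)
  set.seed(child_seed(seed, "anticluster"))
  ids <- rownames(x) %||% make_ids("item", n)
  sizes <- rep(floor(n / K), K) + (seq_len(K) <= n %% K)
  base_assign <- rep.int(seq_len(K), times = sizes)
  rowq <- rowSums(x^2)
  best <- NULL
  for (r in seq_len(restarts)) {
    g <- base_assign[sample.int(n)]
    res <- anticluster_exchange(x, g, K, sizes, rowq, max_sweeps)
    if (is.null(best) || res$objective > best$objective) best <- res
  }
  structure(list(ids = ids, groups = best$groups, K = K,
                 objective_value = best$objective,
                 objective_initial = best$objective_initial,
                 sweeps = best$sweeps),
            class = "anticlustering")
}

# exchange local search; objective O = sum_g (n_g * q_g - ||s_g||^2) where
# q_g = sum of squared norms in g and s_g = coordinate sum of g
anticluster_exchange <- function(x, g, K, sizes, rowq, max_sweeps) {
  d <- ncol(x); n <- nrow(x)
  s <- rowsum(x, g)                      # K x d group sums
  q <- as.numeric(rowsum(rowq, g))       # group sum of squared norms
  contrib <- sizes * q - rowSums(s^2)
  objective <- sum(contrib)
  objective_initial <- objective
  sweeps <- 0L
  if (K >= 2 && max_sweeps > 0) {
    repeat {
      sweeps <- sweeps + 1L
      improved <- FALSE
      for (i in seq_len(n)) {
        a <- g[i]
        others <- which(g != a)
        if (length(others) == 0) next
        xi <- x[i, ]
        gb <- g[others]
        # group a loses i, gains j
        u <- s[a, ] - xi                               # d-vector
        cross_u <- as.numeric(x[others, , drop = FALSE] %*% u)
        new_a <- sizes[a] * (q[a] - rowq[i] + rowq[others]) -
          (sum(u^2) + 2 * cross_u + rowq[others])
        # group b gains i, loses j
        v <- s[gb, , drop = FALSE] + matrix(xi, length(others), d, byrow = TRUE)
        cross_v <- rowSums(x[others, , drop = FALSE] * v)
        new_b <- sizes[gb] * (q[gb] + rowq[i] - rowq[others]) -
          (rowSums(v^2) + rowq[others] - 2 * cross_v)
        delta <- new_a + new_b - contrib[a] - contrib[gb]
        k <- which.max(delta)
        if (delta[k] > 1e-9) {
          j <- others[k]; b <- g[j]
          # apply swap: objective strictly increases
          s[a, ] <- s[a, ] - x[i, ] + x[j, ]
          s[b, ] <- s[b, ] + x[i, ] - x[j, ]
          q[a] <- q[a] - rowq[i] + rowq[j]
          q[b] <- q[b] + rowq[i] - rowq[j]
          g[i] <- b; g[j] <- a
          contrib[a] <- sizes[a] * q[a] - sum(s[a, ]^2)
          contrib[b] <- sizes[b] * q[b] - sum(s[b, ]^2)
          objective <- sum(contrib)
          improved <- TRUE
        }
      }
      if (!improved || sweeps >= max_sweeps) break
    }
  }
  list(groups = g, objective = objective,
       objective_initial = objective_initial, sweeps = sweeps)
}

#' @export
print.anticlustering <- function(x, ...) {
  cat(sprintf("Anticlustering: n = %d, K = %d, objective %.4g (initial %.4g, %d sweep%s)\n",
              length(x$groups), x$K, x$objective_value, x$objective_initial,
              x$sweeps, if (x$sweeps == 1) "" else "s"))
  print(table(group = x$groups))
  invisible(x)
}

# encode a three-value label matrix for distance computations
encode_labels <- function(labels, encoding = c(active = 1, inactive = 0, missing = 0.5)) {
  validate_labels(labels)
  enc <- matrix(encoding[["missing"]], nrow(labels), ncol(labels),
                dimnames = dimnames(labels))
  enc[!is.na(labels) & labels == 1] <- encoding[["active"]]
  enc[!is.na(labels) & labels == 0] <- encoding[["inactive"]]
  enc
}

#' Anticlustering train/test split
#'
#' Runs [anticluster()] on an encoded label matrix (active = 1, inactive = 0,
#' missing = 0.5 by default; optionally augmented with standardized features)
#' and allocates one of the K groups, chosen uniformly at random, as the test
#' set — yielding a `1/K` test fraction whose per-assay label proportions
#' track the training set.
#'
#' @param labels Label matrix over `{1, 0, NA}`.
#' @param K Number of anticlusters (default 5, i.e. an 80/20 split).
#' @param seed Integer seed.
#' @param features Optional numeric feature matrix (same rows as `labels`) to
#'   augment the encoding; columns are standardized before use.
#' @param encoding Named numeric encoding of the three label states.
#' @param max_sweeps,restarts Passed to [anticluster()].
#' @return List with `train_ids`, `test_ids`, `assignment` (the
#'   `anticlustering` object) and `test_group`.
#' @export
split_train_test <- function(labels, K = 5, seed = 1, features = NULL,
                             encoding = c(active = 1, inactive = 0, missing = 0.5),
                             max_sweeps = 20, restarts = 1) {
  enc <- encode_labels(labels, encoding)
  if (!is.null(features)) {
    stopifnot(nrow(features) == nrow(labels))
    enc <- cbind(enc, scale(features))
  }
  ac <- anticluster(enc, K, max_sweeps = max_sweeps, restarts = restarts,
                    seed = child_seed(seed, "split_anticluster"))
  set.seed(child_seed(seed, "split_pick_test"))
  test_group <- sample.int(K, 1)
  list(train_ids = ac$ids[ac$groups != test_group],
       test_ids = ac$ids[ac$groups == test_group],
       assignment = ac, test_group = test_group)
}

#' Anticlustering cross-validation folds
#'
#' As [split_train_test()], but all `K` groups are retained as CV folds, so
#' every fold's label composition tracks the global one.
#'
#' @inheritParams split_train_test
#' @param K Number of folds (default 10).
#' @return Named integer vector: fold index in `1..K` per chemical.
#' @export
make_cv_folds <- function(labels, K = 10, seed = 1, features = NULL,
                          encoding = c(active = 1, inactive = 0, missing = 0.5),
                          max_sweeps = 20, restarts = 1) {
  enc <- encode_labels(labels, encoding)
  if (!is.null(features)) {
    stopifnot(nrow(features) == nrow(labels))
    enc <- cbind(enc, scale(features))
  }
  ac <- anticluster(enc, K, max_sweeps = max_sweeps, restarts = restarts,
                    seed = child_seed(seed, "cv_anticluster"))
  stats::setNames(ac$groups, ac$ids)
}

#' Per-cell target counts for proportion-matched subsetting
#'
#' @param proportions Numeric vector (or matrix) of cell proportions.
#' @param size Subset size.
#' @return Rounded target counts (round half away from zero).
#' @export
#' @examples
#' stratified_targets(c(active = 0.1008, inactive = 0.7354, missing = 0.1638), 748)
stratified_targets <- function(proportions, size) {
  round_half_away(proportions * size)
}

#' Repeated-random stratified subsetting
#'
#' Draws random subsets of size `round(fraction * n)` from the eligible pool
#' until, for every assay, the subset's active/inactive/missing counts are
#' each within `tolerance` of `round(proportion * size)` computed from the
#' full label matrix. Returns the first success, or the best-scoring attempt
#' with a warning after `max_tries` draws.
#'
#' @param labels Label matrix over `{1, 0, NA}`.
#' @param fraction Subset fraction of the full set, in (0, 1).
#' @param tolerance Allowed absolute deviation per assay/state cell.
#' @param max_tries Maximum number of random draws.
#' @param seed Integer seed.
#' @param eligible Optional character vector of chem_ids eligible for
#'   selection (e.g. chemicals with spectra available); default all.
#' @return Character vector of selected chem_ids, with attributes `success`,
#'   `tries`, `max_deviation` and `targets`.
#' @export
stratified_subset <- function(labels, fraction, tolerance = 5, max_tries = 1000,
                              seed = 1, eligible = NULL) {
  validate_labels(labels)
  stopifnot(fraction > 0, fraction < 1, tolerance >= 0, max_tries >= 1)
  n <- nrow(labels)
  size <- as.integer(round_half_away(fraction * n))
  pool <- eligible %||% rownames(labels)
  stopifnot(all(pool %in% rownames(labels)))
  if (length(pool) < size)
    stop("eligible pool smaller than requested subset size", call. = FALSE)
  props <- cell_counts(labels) / n
  targets <- stratified_targets(props, size)
  set.seed(child_seed(seed, "stratified_subset"))
  best <- NULL; best_dev <- Inf; tries <- 0L
  repeat {
    tries <- tries + 1L
    cand <- sample(pool, size)
    dev <- max(abs(cell_counts(labels[cand, , drop = FALSE]) - targets))
    if (dev < best_dev) { best <- cand; best_dev <- dev }
    if (dev <= tolerance || tries >= max_tries) break
  }
  success <- best_dev <= tolerance
  if (!success)
    warning(sprintf(
      "no subset met tolerance %d in %d tries; returning best attempt (max deviation %d)",
      tolerance, max_tries, best_dev))
  structure(best, success = success, tries = tries,
            max_deviation = best_dev, targets = targets)
}

# assay x state count table for a label matrix
cell_counts <- function(labels) {
  rbind(active = colSums(labels == 1, na.rm = TRUE),
        inactive = colSums(labels == 0, na.rm = TRUE),
        missing = colSums(is.na(labels)))
}
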