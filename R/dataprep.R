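# Raw-record deduplication, optional SMARTS fingerprinting, and feature
# filtering (near-zero variance, pairwise correlation).

#' Deduplicate raw records into a label matrix
#'
#' Collapses multiple records per chemical with the screening-panel rule: a
#' chemical is active in an assay if any of its records is active there.
#' Mixed inactive/missing records resolve to inactive by default (an
#' inconclusive run carries no evidence against an observed inactive); set
#' `conflict = "strict"` to resolve them to missing instead. The operation is
#' idempotent.
#'
#' @param records A `RawRecordSet`: data.frame with a `chem_id` column plus one
#'   column per assay over `{1, 0, NA}` (as produced by [inject_duplicates()]),
#'   possibly several rows per chemical.
#' @param conflict `"inactive"` (default) or `"strict"` for the
#'   inactive-vs-missing resolution.
#' @return Label matrix with one row per unique `chem_id` (order of first
#'   appearance).
#' @export
deduplicate <- function(records, conflict = c("inactive", "strict")) {
  conflict <- match.arg(conflict)
  stopifnot(is.data.frame(records), "chem_id" %in% names(records))
  assays <- setdiff(names(records), "chem_id")
  lab <- as.matrix(records[, assays, drop = FALSE])
  bad <- which(!(lab %in% c(0, 1) | is.na(lab)))
  if (length(bad) > 0) {
    row <- ((bad[1] - 1) %% nrow(lab)) + 1
    stop(sprintf("record %d (chem_id %s) has label outside {1, 0, missing}",
                 row, records$chem_id[row]), call. = FALSE)
  }
  ids <- as.character(records$chem_id)
  grp <- factor(ids, levels = unique(ids))
  n1 <- rowsum((lab == 1 & !is.na(lab)) + 0, grp)
  n0 <- rowsum((lab == 0 & !is.na(lab)) + 0, grp)
  nna <- rowsum(is.na(lab) + 0, grp)
  out <- matrix(NA_integer_, nlevels(grp), length(assays),
                dimnames = list(levels(grp), assays))
  out[n1 > 0] <- 1L
  if (conflict == "inactive") {
    out[n1 == 0 & n0 > 0] <- 0L
  } else {
    out[n1 == 0 & n0 > 0 & nna == 0] <- 0L
  }
  out
}

#' Compute binary fingerprints from SMILES by SMARTS substructure matching
#'
#' Sets bit (i, j) to 1 iff chemical i contains at least one match of
#' substructure pattern j. Requires the ChemmineOB (OpenBabel) backend.
#' Unparseable SMILES are reported and dropped, never silently zero-filled;
#' unparseable SMARTS raise a configuration error listing the offending
#' patterns before any matching is attempted.
#'
#' @param smiles Named character vector of SMILES (names are chem_ids), or a
#'   data.frame with columns `chem_id` and `smiles`.
#' @param patterns Named character vector of SMARTS (names are feature_ids),
#'   or a data.frame with columns `feature_id` and `pattern`.
#' @return Binary fingerprint table; chemicals whose SMILES failed to parse
#'   are listed in the `"dropped"` attribute and a warning.
#' @export
compute_fingerprints <- function(smiles, patterns) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("compute_fingerprints requires the ChemmineOB backend", call. = FALSE)
  if (is.data.frame(smiles)) smiles <- stats::setNames(smiles$smiles, smiles$chem_id)
  if (is.data.frame(patterns)) patterns <- stats::setNames(patterns$pattern, patterns$feature_id)
  if (is.null(names(smiles))) names(smiles) <- make_ids("chem", length(smiles))
  if (is.null(names(patterns))) names(patterns) <- make_ids("fp", length(patterns))
  parse_mol <- function(s) tryCatch({
    m <- ChemmineOB::forEachMol("SMILES", s, identity)
    fmla <- ChemmineOB::prop_OB(m)$formula
    if (is.null(fmla) || !nzchar(fmla)) NULL else m
  }, error = function(e) NULL)
  mols <- lapply(smiles, parse_mol)
  ok <- !vapply(mols, is.null, logical(1))
  if (any(!ok))
    warning("dropped unparseable SMILES for: ",
            paste(names(smiles)[!ok], collapse = ", "))
  mols <- mols[ok]
  if (length(mols) == 0) stop("no parseable SMILES supplied", call. = FALSE)
  probe <- mols[[1]]
  bad_pat <- names(patterns)[vapply(patterns, function(p)
    inherits(tryCatch(ChemmineOB::smartsSearch_OB(probe, p),
                      error = function(e) e), "error"), logical(1))]
  if (length(bad_pat) > 0)
    stop("unparseable SMARTS patterns: ", paste(bad_pat, collapse = ", "),
         call. = FALSE)
  bits <- matrix(0L, length(mols), length(patterns),
                 dimnames = list(names(mols), names(patterns)))
  for (j in seq_along(patterns)) {
    bits[, j] <- vapply(mols, function(m)
      as.integer(ChemmineOB::smartsSearch_OB(m, patterns[[j]]) >= 1), integer(1))
  }
  attr(bits, "dropped") <- names(smiles)[!ok]
  bits
}

#' Remove zero- and near-zero-variance features
#'
#' A feature is removed if it has a single unique value, or if the ratio of
#' its most frequent to second most frequent value exceeds `freq_cut` while
#' its percentage of distinct values is below `unique_cut`. For binary
#' features this reduces to minority prevalence below `1 / (freq_cut + 1)`.
#'
#' @param table Binary fingerprint table.
#' @param freq_cut Frequency-ratio cutoff (default 19, i.e. 95/5).
#' @param unique_cut Percent-distinct cutoff (default 10).
#' @return List with the filtered `table` and a `report` (removed/surviving
#'   feature ids).
#' @export
filter_near_zero_variance <- function(table, freq_cut = 19, unique_cut = 10) {
  stopifnot(is.matrix(table), nrow(table) > 0, ncol(table) > 0)
  n <- nrow(table)
  nzv <- vapply(seq_len(ncol(table)), function(j) {
    tab <- sort(table(table[, j]), decreasing = TRUE)
    if (length(tab) < 2) return(TRUE)
    ratio <- tab[1] / tab[2]
    pct_unique <- 100 * length(tab) / n
    ratio > freq_cut && pct_unique < unique_cut
  }, logical(1))
  report <- list(removed_near_zero = colnames(table)[nzv],
                 removed_correlated = character(0),
                 cutoff = NA_real_,
                 surviving = colnames(table)[!nzv])
  list(table = table[, !nzv, drop = FALSE], report = report)
}

#' Remove highly correlated features
#'
#' Iterative exhaustive-recompute variant: while any surviving pair has
#' absolute Pearson correlation above `cutoff`, the pair with the largest
#' absolute correlation is found and the member with the larger mean absolute
#' correlation to all remaining features is removed (ties break toward the
#' lower column index). Guarantees no surviving pair exceeds `cutoff`. On
#' binary columns Pearson correlation is the phi coefficient; constant
#' columns correlate 0 by convention.
#'
#' @param table Fingerprint table with at least 2 features.
#' @param cutoff Absolute correlation cutoff in (0, 1).
#' @return List with the filtered `table` and a `report`.
#' @export
filter_correlated <- function(table, cutoff) {
  stopifnot(is.matrix(table), ncol(table) >= 2, cutoff > 0, cutoff < 1)
  cm <- suppressWarnings(abs(stats::cor(table)))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 0
  removed <- character(0)
  keep <- seq_len(ncol(table))
  repeat {
    sub <- cm[keep, keep, drop = FALSE]
    mx <- max(sub)
    if (mx <= cutoff || length(keep) < 2) break
    hit <- which(sub == mx, arr.ind = TRUE)[1, ]
    i <- keep[hit[1]]; j <- keep[hit[2]]
    mean_i <- mean(cm[i, setdiff(keep, i)])
    mean_j <- mean(cm[j, setdiff(keep, j)])
    drop_idx <- if (mean_i > mean_j) i else if (mean_j > mean_i) j else min(i, j)
    removed <- c(removed, colnames(table)[drop_idx])
    keep <- setdiff(keep, drop_idx)
  }
  report <- list(removed_near_zero = character(0),
                 removed_correlated = removed,
                 cutoff = cutoff,
                 surviving = colnames(table)[keep])
  list(table = table[, keep, drop = FALSE], report = report)
}
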