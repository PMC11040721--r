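# Internal helpers shared across modules.

#' Derive a child seed from a top-level seed and a stage label
#'
#' A single global integer seed fans out to per-stage child seeds through this
#' documented splitting rule, so any stage of a run can be regenerated
#' independently of the others. The rule is a fixed affine hash of the stage
#' label folded into the Lehmer modulus, keeping results in 32-bit integer
#' range.
#'
#' @param seed Integer top-level seed.
#' @param stage Character label of the stage (e.g. `"fingerprints"`).
#' @return An integer seed, deterministic in `(seed, stage)`.
#' @export
#' @examples
#' child_seed(1, "fingerprints")
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 104729
  m <- 2147483647
  as.integer(((abs(seed) %% m) * 48271 + h) %% m)
}

sigmoid <- function(x) stats::plogis(x)

logit <- function(p) stats::qlogis(p)

# round half away from zero (R's round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_prob <- function(p, what = "p") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("all values of %s must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(p)
}

make_ids <- function(prefix, n) sprintf("%s_%0*d", prefix, max(4L, nchar(n)), seq_len(n))

# validate a chemicals x features binary table
validate_bits <- function(bits) {
  stopifnot(is.matrix(bits))
  if (is.null(rownames(bits)) || is.null(colnames(bits)))
    stop("fingerprint table must have chem_id rownames and feature_id colnames")
  if (anyDuplicated(colnames(bits))) stop("duplicate feature_ids in fingerprint table")
  if (!all(bits %in% c(0L, 1L))) stop("fingerprint bits must be 0 or 1")
  invisible(bits)
}

validate_probs <- function(probs) {
  stopifnot(is.matrix(probs))
  if (is.null(rownames(probs)) || is.null(colnames(probs)))
    stop("probability table must have chem_id rownames and feature_id colnames")
  check_prob(probs, "fingerprint probabilities")
  invisible(probs)
}

validate_labels <- function(labels) {
  stopifnot(is.matrix(labels))
  if (is.null(rownames(labels)) || is.null(colnames(labels)))
    stop("label matrix must have chem_id rownames and assay_id colnames")
  obs <- labels[!is.na(labels)]
  if (!all(obs %in% c(0, 1))) stop("labels must be 1 (active), 0 (inactive) or NA (missing)")
  invisible(labels)
}
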