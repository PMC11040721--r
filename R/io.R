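# TSV readers/writers for the pipeline's table schemas: first column
# `chem_id`, remaining columns feature or assay ids; missing labels written
# as NaN, with empty strings also accepted on read.

#' Write a chemicals-by-columns table as TSV
#'
#' @param table Matrix with chem_id rownames (fingerprints, probabilities,
#'   labels or scores). Missing values are written as `NaN`.
#' @param path Output file.
#' @export
write_table_tsv <- function(table, path) {
  df <- data.frame(chem_id = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NaN")
  invisible(path)
}

#' Read a chemicals-by-columns TSV table
#'
#' @param path TSV with a header row and a `chem_id` first column; `NaN` and
#'   empty cells are read as missing.
#' @param integer Coerce entries to integer (for bit/label tables).
#' @return Matrix with chem_id rownames.
#' @export
read_table_tsv <- function(path, integer = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("NaN", "NA", ""),
                          stringsAsFactors = FALSE)
  stopifnot("chem_id" %in% names(df))
  m <- as.matrix(df[, setdiff(names(df), "chem_id"), drop = FALSE])
  rownames(m) <- as.character(df$chem_id)
  if (integer) storage.mode(m) <- "integer" else storage.mode(m) <- "double"
  m
}

#' Write a group assignment as two-column TSV
#'
#' @param assignment An `anticlustering` object or a named vector of group
#'   indices.
#' @param path Output file.
#' @export
write_assignment_tsv <- function(assignment, path) {
  if (inherits(assignment, "anticlustering")) {
    df <- data.frame(chem_id = assignment$ids, group = assignment$groups)
  } else {
    df <- data.frame(chem_id = names(assignment), group = as.integer(assignment))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# planted ground truth as JSON (sparse weights only)
write_truth_json <- function(model, path) {
  w <- model$weights
  sparse <- lapply(colnames(w), function(a) {
    nz <- which(w[, a] != 0)
    list(features = rownames(w)[nz], weights = unname(w[nz, a]),
         intercept = unname(model$intercepts[[a]]))
  })
  names(sparse) <- colnames(w)
  jsonlite::write_json(list(assays = sparse,
                            shared_feature_ids = model$shared_feature_ids,
                            target_prevalence = as.list(model$target_prevalence)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
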