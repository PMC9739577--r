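# Tab-separated readers and writers for the expression, clinical and result
# tables. All readers reject duplicated IDs and malformed cells with the
# offending location; read/write round-trips are identities (asserted in
# tests).

#' Read a log2 expression matrix from TSV
#'
#' Expected layout: header line with `gene_id` then sample IDs; one row per
#' gene; tab-separated; `NA` for missing values.
#'
#' @param path File path.
#' @return Numeric genes x samples matrix with dimnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 2, "expression TSV needs gene_id plus >= 1 sample column")
  assert_that(names(df)[1] == "gene_id",
              "first column of an expression TSV must be 'gene_id'")
  if (anyDuplicated(df$gene_id)) {
    dup <- which(duplicated(df$gene_id))[1]
    stop(sprintf("duplicate gene_id '%s' at data row %d of %s",
                 df$gene_id[dup], dup, path), call. = FALSE)
  }
  if (anyDuplicated(names(df)[-1])) {
    stop(sprintf("duplicate sample column '%s' in %s",
                 names(df)[-1][duplicated(names(df)[-1])][1], path),
         call. = FALSE)
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(!is.na(vals[[j]]) & is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      stop(sprintf("non-numeric expression cell in column '%s', data row %d of %s",
                   names(vals)[j], bad, path), call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- df$gene_id
  validate_expression(m)
}

#' Write an expression matrix to TSV
#'
#' @param expr Genes x samples matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

clinical_columns <- c("sample_id", "os_time", "os_event", "rfs_time",
                      "rfs_event", "subtype")

#' Read a clinical table from TSV
#'
#' Columns: `sample_id`, `os_time`, `os_event`, `rfs_time`, `rfs_event`,
#' `subtype`. Times are non-negative (months by convention; the package
#' treats them as unitless), events are 0/1, `NA` allowed.
#'
#' @param path File path.
#' @return Data frame with validated columns.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(clinical_columns, names(df))
  assert_that(length(missing_cols) == 0,
              sprintf("clinical TSV missing column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(df$sample_id)) {
    dup <- which(duplicated(df$sample_id))[1]
    stop(sprintf("duplicate sample_id '%s' at data row %d of %s",
                 df$sample_id[dup], dup, path), call. = FALSE)
  }
  for (col in c("os_event", "rfs_event")) {
    bad <- which(!is.na(df[[col]]) & !df[[col]] %in% c(0, 1))[1]
    if (!is.na(bad)) {
      stop(sprintf("non-binary %s at data row %d of %s", col, bad, path),
           call. = FALSE)
    }
  }
  for (col in c("os_time", "rfs_time")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)[1]
    if (!is.na(bad)) {
      stop(sprintf("negative %s at data row %d of %s", col, bad, path),
           call. = FALSE)
    }
  }
  df[, clinical_columns]
}

#' Write a clinical table to TSV
#'
#' @param clinical Data frame with the standard clinical columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  assert_that(all(clinical_columns %in% names(clinical)),
              "clinical table missing standard columns")
  utils::write.table(clinical[, clinical_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a stratification result to TSV
#'
#' @param strat A `stratification_result` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stratification <- function(strat, path) {
  utils::write.table(as.data.frame(strat), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a stratification result written by [write_stratification()]
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_stratification <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "count_low", "p_low", "ra_call", "count_high",
              "p_high", "erk_call", "category")
  assert_that(all(needed %in% names(df)),
              "stratification TSV missing standard columns")
  df
}
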