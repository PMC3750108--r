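sniff_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a delimited numeric data table
#'
#' Reads a tab- or comma-separated (sniffed from the header line) table with
#' one header row of variable names and one leading column of observation
#' labels, into a numeric matrix with dimnames. Observations are rows. Any
#' missing or non-numeric cell is an error naming its coordinates: values are
#' rejected rather than imputed.
#'
#' @param path Path to the file.
#' @param orientation `"observations_in_rows"` (the stored layout, default) or
#'   `"observations_in_columns"` (the table is transposed after reading).
#' @return A numeric matrix with row and column names.
#' @export
read_data_table <- function(path,
                            orientation = c("observations_in_rows",
                                            "observations_in_columns")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("data table not found: ", path)
  sep <- sniff_sep(path)
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                 path, bad, nf[bad], nf[1]))
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", row.names = NULL,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("data table needs a label column and at least one variable")
  row_ids <- df[[1]]
  col_ids <- colnames(df)[-1]
  if (anyDuplicated(row_ids)) {
    stop("duplicate observation label(s): ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  }
  if (anyDuplicated(col_ids)) {
    stop("duplicate variable label(s): ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-numeric or missing value '%s' at row '%s', column '%s'",
      vals[bad[1, 1], bad[1, 2]], row_ids[bad[1, 1]], col_ids[bad[1, 2]]
    ))
  }
  dimnames(num) <- list(row_ids, col_ids)
  if (orientation == "observations_in_columns") num <- t(num)
  num
}

#' Write a numeric data table
#'
#' Inverse of [read_data_table()]: tab-separated, full double precision, one
#' header row and one leading label column; round-trips exactly through the
#' reader (to the precision of decimal representation, < 1e-15 relative).
#'
#' @param values Numeric matrix with row and column names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_data_table <- function(values, path) {
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must be a matrix with row and column names")
  }
  header <- paste(c("id", colnames(values)), collapse = "\t")
  body <- vapply(seq_len(nrow(values)), function(i) {
    paste(c(rownames(values)[i], sprintf("%.17g", values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the EFM selection report of a fitted PLP model
#'
#' One row per selected EFM in selection order with columns `efm_id`, `n_lv`,
#' `r2`, `p_value`, `var_lambda_pct`, `cum_var_R_pct` (the familiar audit-table
#' layout: inner latent variables used, correlation diagnostics, explained
#' weighting-factor variance and the cumulative explained flux variance).
#'
#' @param model A fitted `plp_model` from [select_efms()].
#' @param path Output path (tab-separated).
#' @return Invisibly, `path`.
#' @export
write_selection_report <- function(model, path) {
  stopifnot(inherits(model, "plp_model"))
  tab <- selection_table(model)
  header <- paste(colnames(tab), collapse = "\t")
  body <- vapply(seq_len(nrow(tab)), function(i) {
    paste(c(sprintf("%d", tab$efm_id[i]), sprintf("%d", tab$n_lv[i]),
            sprintf("%.17g", tab$r2[i]), sprintf("%.17g", tab$p_value[i]),
            sprintf("%.17g", tab$var_lambda_pct[i]),
            sprintf("%.17g", tab$cum_var_R_pct[i])), collapse = "\t")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read back a selection report written by [write_selection_report()]
#'
#' @param path Path to a report file.
#' @return A data frame with the report columns.
#' @export
read_selection_report <- function(path) {
  if (!file.exists(path)) stop("report not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  expected <- c("efm_id", "n_lv", "r2", "p_value", "var_lambda_pct", "cum_var_R_pct")
  if (!identical(colnames(df), expected)) {
    stop("unexpected report columns: ", paste(colnames(df), collapse = ", "))
  }
  df
}

#' Selection diagnostics of a PLP model as a data frame
#'
#' @param model A fitted `plp_model`.
#' @return Data frame with one row per selected EFM, in selection order.
#' @export
selection_table <- function(model) {
  stopifnot(inherits(model, "plp_model"))
  sel <- model$selected
  data.frame(
    efm_id = vapply(sel, function(s) s$efm_id, integer(1)),
    n_lv = vapply(sel, function(s) s$score$n_lv, integer(1)),
    r2 = vapply(sel, function(s) s$score$r2, numeric(1)),
    p_value = vapply(sel, function(s) s$score$p_value, numeric(1)),
    var_lambda_pct = vapply(sel, function(s) s$score$var_lambda_pct, numeric(1)),
    cum_var_R_pct = model$cum_var_R_pct,
    stringsAsFactors = FALSE
  )
}

#' Write an EFM set as a delimited table
#'
#' Layout is reactions x EFM with a header row of EFM ids, compatible with
#' [read_data_table()] / [read_efm_table()].
#'
#' @param efms An `efm_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_efm_table <- function(efms, path) {
  stopifnot(inherits(efms, "efm_set"))
  m <- efms$EM
  dimnames(m) <- list(efms$reaction_ids, paste0("efm_", efms$efm_ids))
  write_data_table(m, path)
}

#' Read an EFM set from a delimited table
#'
#' Expects the layout written by [write_efm_table()]: reactions in rows, EFM in
#' columns, column headers either bare integers or `efm_<k>`. No stoichiometric
#' validation is attempted (tables of modes in reduced, measured-flux form do
#' not carry the network).
#'
#' @param path Path to the table.
#' @return An `efm_set`.
#' @export
read_efm_table <- function(path) {
  m <- read_data_table(path)
  ids <- sub("^efm_", "", colnames(m))
  ids_num <- suppressWarnings(as.integer(ids))
  if (anyNA(ids_num)) ids_num <- seq_len(ncol(m))
  efm_set(unname(m), reaction_ids = rownames(m), efm_ids = ids_num)
}
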