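#' Read a sample table from CSV
#'
#' Reads an RFC-4180 CSV with a header row and renames columns to the
#' package's canonical names via `columns`, a named character vector/list
#' mapping canonical name -> file column name. Missing required columns
#' raise a schema error listing the absent names.
#'
#' @param path CSV file path.
#' @param columns Optional mapping, e.g.
#'   `c(bulk_density = "BD", gravimetric_wc = "U")`. Columns not mentioned
#'   keep their file names.
#' @param required Canonical column names that must be present after
#'   mapping.
#' @return A data frame.
#' @export
read_samples_csv <- function(path, columns = NULL,
                             required = c("structure", "bulk_density",
                                          "gravimetric_wc", "matric_potential")) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(columns)) {
    columns <- unlist(columns)
    for (canon in names(columns)) {
      src <- columns[[canon]]
      if (src %in% names(tab)) names(tab)[names(tab) == src] <- canon
    }
  }
  check_columns(tab, required, paste0("'", basename(path), "'"))
  tab
}

#' Write a sample or results table to CSV
#'
#' @param tab Data frame.
#' @param path Output path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(tab, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Serialize fitted parameters to JSON
#'
#' Writes a [busscher_params()], [gaussian_surface_params()] or
#' `evaluation_report` object to JSON at full double precision, so that
#' [read_params_json()] round-trips the numbers exactly.
#'
#' @param params Parameter or report object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  payload <- unclass(params)
  payload$.class <- class(params)[1]
  if (!is.null(payload$se)) payload$se <- as.list(payload$se)
  # I(17) significant digits: doubles survive the text round trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read fitted parameters back from JSON
#'
#' @param path JSON file written by [write_params_json()].
#' @return The reconstructed object, with its original class.
#' @export
read_params_json <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- payload$.class
  payload$.class <- NULL
  if (!is.null(payload$se)) payload$se <- vapply(payload$se, as.double, 1)
  if (is.null(payload$flags)) payload$flags <- character()
  for (nm in c("a", "b", "c", "x0", "y0", "r2", "r2_sst", "rmse", "crm",
               "r", "d"))
    if (!is.null(payload[[nm]])) payload[[nm]] <- as.double(payload[[nm]])
  switch(cls,
    busscher_params = busscher_params(
      payload$a, payload$b, payload$c,
      payload$structure %||% NA_character_, payload$se,
      r2 = payload$r2 %||% NA_real_, r2_sst = payload$r2_sst %||% NA_real_,
      rmse = payload$rmse %||% NA_real_),
    gaussian_surface_params = gaussian_surface_params(
      payload$a, payload$b, payload$c, payload$x0, payload$y0,
      payload$structure %||% NA_character_, payload$se,
      r2 = payload$r2 %||% NA_real_),
    evaluation_report = structure(
      list(n = payload$n, rmse = payload$rmse %||% NA_real_,
           crm = payload$crm %||% NA_real_, r = payload$r %||% NA_real_,
           d = payload$d %||% NA_real_, flags = payload$flags),
      class = "evaluation_report"),
    stop_invalid("unknown serialized class: ", cls))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
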