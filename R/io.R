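#' Read a count dataset from a delimited file
#'
#' Reads a header-ed delimited table, extracts the response and predictor
#' columns, and validates the count contract: the response must be
#' non-negative integers with no missing values. Violations are reported
#' with their row numbers.
#'
#' @param path File path.
#' @param response,predictor Column names holding the counts and the
#'   explanatory variable (defaults `"y"` and `"x"`).
#' @param kind `"oneway"`, `"regression"`, or `NULL` to infer from the
#'   predictor type (numeric implies regression).
#' @param delim Field delimiter (default comma).
#' @return A validated count dataset tibble (columns `y`, `x`) with `kind`
#'   and `id` attributes.
#' @export
read_count_data <- function(path, response = "y", predictor = "x",
                            kind = NULL, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  for (col in c(response, predictor)) {
    if (!col %in% names(raw)) {
      abort(sprintf("Column '%s' not found in %s.", col, path))
    }
  }
  y_raw <- raw[[response]]
  x <- raw[[predictor]]

  missing_rows <- which(is.na(y_raw) | is.na(x))
  if (length(missing_rows) > 0) {
    abort(sprintf("Missing values in row(s): %s.",
                  paste(utils::head(missing_rows, 5), collapse = ", ")))
  }
  y_num <- suppressWarnings(as.numeric(y_raw))
  bad <- which(is.na(y_num) | y_num < 0 | y_num != round(y_num))
  if (length(bad) > 0) {
    abort(sprintf(
      "Response '%s' must be non-negative integers; offending row(s): %s.",
      response, paste(utils::head(bad, 5), collapse = ", ")
    ))
  }

  if (!is.null(kind)) {
    kind <- match.arg(kind, c("oneway", "regression"))
    if (kind == "regression" && !is.numeric(x)) {
      x_num <- suppressWarnings(as.numeric(x))
      if (any(is.na(x_num))) {
        abort("`kind = \"regression\"` needs a numeric predictor.")
      }
      x <- x_num
    }
    if (kind == "oneway" && is.numeric(x)) x <- as.character(x)
  }

  out <- tibble(y = as.integer(y_num), x = x)
  attr(out, "id") <- basename(path)
  if (!is.null(kind)) attr(out, "kind") <- kind
  validate_count_dataset(out)
}

#' Write a count dataset to a delimited file
#'
#' Writes columns `y` and `x` with a header row at full precision, so a
#' write/read round trip reproduces the dataset exactly.
#'
#' @param data A count dataset.
#' @param path Destination file.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_count_data <- function(data, path, delim = ",") {
  data <- validate_count_dataset(data)
  out <- data[, c("y", "x")]
  if (is.factor(out$x)) out$x <- as.character(out$x)
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}
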