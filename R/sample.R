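#' Construct a sample for network-based frequency analysis
#'
#' A sample is an ordered multiset of finite real values plus a free-text
#' label. Non-finite values (`NA`, `NaN`, `Inf`) are rejected at ingestion:
#' the similarity rule |x_i - x_j| <= zeta is undefined for them.
#'
#' @param values numeric vector, length >= 1, all finite.
#' @param label free-text provenance label.
#' @return an object of class `nb_sample` with elements `values`, `n`,
#'   `label`.
#' @examples
#' s <- nb_sample(c(1, 2, 4), label = "toy")
#' s$n
#' @export
nb_sample <- function(values, label = "sample") {
  if (length(values) == 0) {
    nb_abort("sample must contain at least one value", "netfreq_invalid_input")
  }
  if (!is.numeric(values)) {
    nb_abort("sample values must be numeric", "netfreq_invalid_input")
  }
  values <- as.numeric(values)
  if (!all(is.finite(values))) {
    nb_abort("sample values must all be finite (no NA/NaN/Inf)",
             "netfreq_invalid_input")
  }
  structure(
    list(values = values, n = length(values), label = as.character(label)[1]),
    class = "nb_sample"
  )
}

as_nb_sample <- function(x, label = "sample") {
  if (inherits(x, "nb_sample")) x else nb_sample(x, label = label)
}

#' @export
print.nb_sample <- function(x, ...) {
  cat(sprintf("<nb_sample '%s': n = %d, range [%g, %g]>\n",
              x$label, x$n, min(x$values), max(x$values)))
  invisible(x)
}

#' Read one numeric column from a delimited text file
#'
#' Parses a single column from CSV/TSV-like input. Rows whose cell does not
#' parse as a finite number are counted and reported via the `n_rejected`
#' attribute (and a message), never silently dropped without trace. With
#' `log_transform = TRUE`, non-positive values are excluded (counted in
#' `n_nonpositive`) and the natural log is applied; the returned sample's
#' label records the scale.
#'
#' @param path path to a delimited text file.
#' @param column column name (requires a header row) or 1-based index.
#' @param delimiter field separator; `","` (default) or e.g. `"\t"`.
#' @param log_transform analyse `log(x)` instead of `x`?
#' @param header does the file have a header row? Defaults to `TRUE` when
#'   `column` is a name, `FALSE` when it is an index.
#' @return an `nb_sample` with attributes `n_rejected` and `n_nonpositive`.
#' @export
read_values <- function(path, column = 1, delimiter = ",",
                        log_transform = FALSE,
                        header = is.character(column)) {
  if (!file.exists(path)) {
    nb_abort(sprintf("input file not found: %s", path), "netfreq_io_error")
  }
  df <- tryCatch(
    utils::read.table(path, sep = delimiter, header = header,
                      colClasses = "character", quote = "\"",
                      comment.char = "", check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) nb_abort(sprintf("could not parse '%s': %s",
                                         path, conditionMessage(e)),
                                 "netfreq_io_error")
  )
  if (is.character(column)) {
    if (!column %in% names(df)) {
      nb_abort(sprintf("column '%s' not found (columns: %s)",
                       column, paste(names(df), collapse = ", ")),
               "netfreq_config_error")
    }
    raw <- df[[column]]
  } else {
    column <- as.integer(column)
    if (column < 1 || column > ncol(df)) {
      nb_abort(sprintf("column index %d out of range (file has %d columns)",
                       column, ncol(df)), "netfreq_config_error")
    }
    raw <- df[[column]]
  }
  vals <- suppressWarnings(as.numeric(raw))
  ok <- is.finite(vals)
  n_rejected <- sum(!ok)
  vals <- vals[ok]
  if (length(vals) == 0) {
    nb_abort("no parseable numeric values in the selected column",
             "netfreq_ingestion_error")
  }
  n_nonpositive <- 0L
  scale <- "natural"
  if (isTRUE(log_transform)) {
    pos <- vals > 0
    n_nonpositive <- sum(!pos)
    vals <- log(vals[pos])
    scale <- "log"
    if (length(vals) == 0) {
      nb_abort("no positive values left to log-transform",
               "netfreq_ingestion_error")
    }
  }
  if (n_rejected > 0) {
    message(sprintf("read_values: %d row(s) failed numeric parsing and were excluded",
                    n_rejected))
  }
  if (n_nonpositive > 0) {
    message(sprintf("read_values: %d non-positive value(s) excluded before log transform",
                    n_nonpositive))
  }
  s <- nb_sample(vals, label = sprintf("%s [%s scale]", basename(path), scale))
  attr(s, "n_rejected") <- n_rejected
  attr(s, "n_nonpositive") <- n_nonpositive
  attr(s, "scale") <- scale
  s
}
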