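#' Read raw p-values from a text file
#'
#' Accepts either a plain text file with one p-value per line, or a
#' delimited CSV/TSV file with a named column (delimiter inferred from the
#' file extension: comma for \code{.csv}, tab otherwise). The tokens
#' \code{NA} and empty fields are treated as missing and handled per
#' \code{naPolicy}; any other unparseable value is a parse error naming the
#' offending line, and values outside [0, 1] are validation errors naming
#' the line.
#'
#' @param path path to the input file.
#' @param column name of the column holding the p-values; NULL (default) for
#'   one-value-per-line input.
#' @param naPolicy,tiesMethod,tieSeed passed to \code{\link{PValueSet}}.
#' @return a \code{\linkS4class{PValueSet}}.
#' @export
readPValues <- function(path, column = NULL, naPolicy = "remove",
                        tiesMethod = "random", tieSeed = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(column)) {
    lines <- trimws(readLines(path, warn = FALSE))
    lineNo <- seq_along(lines)
    nonEmptyTail <- max(c(0L, which(lines != "")))
    lines <- lines[seq_len(nonEmptyTail)]
    lineNo <- lineNo[seq_len(nonEmptyTail)]
    isNA <- lines %in% c("", "NA", "na", "NaN")
    vals <- suppressWarnings(as.numeric(lines))
    vals[isNA] <- NA_real_
    badParse <- which(is.na(vals) & !isNA)
    if (length(badParse))
      stop("cannot parse p-value on line ", lineNo[badParse[1]], ": '",
           lines[badParse[1]], "'", call. = FALSE)
    badRange <- which(!is.na(vals) & (vals < 0 | vals > 1))
    if (length(badRange))
      stop("p-value outside [0, 1] on line ", lineNo[badRange[1]], ": ",
           vals[badRange[1]], call. = FALSE)
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            comment.char = "#", stringsAsFactors = FALSE)
    if (!column %in% names(df))
      stop("column '", column, "' not found in ", path, call. = FALSE)
    vals <- df[[column]]
    if (!is.numeric(vals))
      stop("column '", column, "' is not numeric", call. = FALSE)
    badRange <- which(!is.na(vals) & (vals < 0 | vals > 1))
    if (length(badRange))
      stop("p-value outside [0, 1] in row ", badRange[1], " of column '",
           column, "'", call. = FALSE)
  }
  PValueSet(vals, naPolicy = naPolicy, tiesMethod = tiesMethod,
            tieSeed = tieSeed)
}

#' Write an FDRResult to a delimited file
#'
#' One row per feature with deterministic column order \code{feature},
#' \code{raw_p}, \code{adjusted_p}, \code{fdr}, optionally
#' \code{lower_bound_fdr}, then \code{reject}. Header metadata (method,
#' threshold, pi0, pi0 method) is written as commented lines. Numbers are
#' written at full double precision, so re-reading reproduces the vectors
#' exactly.
#'
#' @param result an \code{\linkS4class{FDRResult}}.
#' @param path output path.
#' @param format \code{"csv"} (default) or \code{"tsv"}.
#' @param sort order rows by increasing FDR estimate; default FALSE.
#' @param justFdr write only the \code{fdr} column; default FALSE.
#' @param lowerBound include the lower-bound column when the result carries
#'   one; default TRUE.
#' @return the path, invisibly.
#' @seealso \code{\link{readResults}}
#' @export
writeResults <- function(result, path, format = c("csv", "tsv"),
                         sort = FALSE, justFdr = FALSE, lowerBound = TRUE) {
  stopifnot(is(result, "FDRResult"))
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  df <- as.data.frame(result)
  if (!lowerBound) df$lower_bound_fdr <- NULL
  if (sort) df <- df[order(df$fdr), , drop = FALSE]
  if (justFdr) df <- df[, "fdr", drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(paste0("# method: ", result@method),
               paste0("# threshold: ", sprintf("%.17g", result@threshold)),
               paste0("# pi0: ", sprintf("%.17g", result@pi0)),
               paste0("# pi0.method: ", result@pi0Method)), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a results table written by writeResults
#'
#' @param path path to the file.
#' @param format \code{"csv"} (default) or \code{"tsv"}.
#' @return data.frame of the table body (metadata lines are skipped).
#' @export
readResults <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  utils::read.table(path, header = TRUE,
                    sep = if (format == "csv") "," else "\t",
                    comment.char = "#", stringsAsFactors = FALSE)
}
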