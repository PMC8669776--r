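#' Construct a PValueSet
#'
#' Validates a vector of raw p-values, applies the missing-value policy and
#' records the tie-handling configuration used whenever ranks are derived
#' from the set.
#'
#' @param values numeric vector of raw p-values in [0, 1]; may contain NA.
#' @param naPolicy \code{"remove"} (default) drops NA entries so that the
#'   feature count \code{m} counts only retained values; \code{"fail"} raises
#'   an error on any NA. Note that removal changes every \code{m}-dependent
#'   adjustment, which is precisely the point: missing entries are not viable
#'   features.
#' @param tiesMethod how tied p-values are ranked; one of \code{"first"},
#'   \code{"last"}, \code{"average"}, \code{"min"}, \code{"max"},
#'   \code{"random"} (default). With \code{"random"}, tied blocks receive a
#'   random permutation of their rank range.
#' @param tieSeed integer seed for the \code{"random"} ties method. When NULL
#'   an internal fixed seed is used so repeated calls agree.
#'
#' @return a \code{\linkS4class{PValueSet}}.
#' @examples
#' pset <- PValueSet(c(0.005, 0.049, 0.050, 0.051, 0.700))
#' nFeatures(pset)
#' @export
PValueSet <- function(values, naPolicy = c("remove", "fail"),
                      tiesMethod = c("random", "first", "last", "average",
                                     "min", "max"),
                      tieSeed = NULL) {
  naPolicy <- match.arg(naPolicy)
  tiesMethod <- match.arg(tiesMethod)
  if (!is.numeric(values))
    stop("p-values must be numeric", call. = FALSE)
  values <- as.numeric(values)
  if (anyNA(values)) {
    if (naPolicy == "fail")
      stop("NA p-values present and naPolicy = \"fail\"", call. = FALSE)
    values <- values[!is.na(values)]
  }
  if (!length(values))
    stop("no p-values remain after applying the NA policy", call. = FALSE)
  bad <- which(values < 0 | values > 1)
  if (length(bad))
    stop("p-values outside [0, 1] at position(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  seed <- if (is.null(tieSeed)) .DEFAULT_TIE_SEED else as.integer(tieSeed)
  new("PValueSet", values = values, tiesMethod = tiesMethod, tieSeed = seed)
}

#' @describeIn PValueSet the retained p-values.
#' @param object a \code{PValueSet}.
#' @export
setMethod("pvalues", "PValueSet", function(object, ...) object@values)

#' @describeIn PValueSet the number of retained features m.
#' @export
setMethod("nFeatures", "PValueSet", function(object) length(object@values))

setMethod("show", "PValueSet", function(object) {
  m <- length(object@values)
  cat("PValueSet with", m, "p-value(s)\n")
  cat("  range: [", format(min(object@values)), ",",
      format(max(object@values)), "]\n")
  cat("  ties.method:", object@tiesMethod, "\n")
  invisible(NULL)
})
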