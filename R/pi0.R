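#' Scott's normal reference rule bin count on [0, 1]
#'
#' Bin width \eqn{h = 3.49 \cdot sd(p) \cdot m^{-1/3}} translated into
#' \eqn{B = \lceil 1/h \rceil} equal-width bins spanning [0, 1] (anchored at
#' 0 and 1). Falls back to \eqn{B = \lceil \sqrt{m} \rceil} when the sample
#' standard deviation is 0 or the rule's width reaches 1, where a one-bin
#' histogram would be useless for pi0 estimation.
#'
#' @param pset a \code{\linkS4class{PValueSet}} or numeric vector with at
#'   least 2 values.
#' @return positive integer bin count B.
#' @examples
#' scottBinCount(seq(0.001, 0.999, length.out = 1000))  # 10
#' @export
scottBinCount <- function(pset) {
  pset <- .asPValueSet(pset)
  p <- pset@values
  m <- length(p)
  if (m < 2) stop("at least 2 p-values are required", call. = FALSE)
  s <- stats::sd(p)
  h <- 3.49 * s * m^(-1 / 3)
  if (s == 0 || h >= 1) return(as.integer(ceiling(sqrt(m))))
  as.integer(ceiling(1 / h))
}

# Internal: counts of p-values in B equal-width bins over [0,1]; half-open
# [a, b) with the final bin closed so p = 1 lands in bin B.
.binCounts <- function(p, B) {
  idx <- pmin(B, floor(p * B) + 1L)
  tabulate(idx, nbins = B)
}

#' Last Histogram Height pi0 estimator
#'
#' Estimates the null proportion from the occupancy of the p-value histogram
#' bin adjacent to 1. Under the null, p-values are uniform on [0, 1], so
#' each of B equal-width bins is expected to hold \eqn{\pi_0 m / B} null
#' p-values, while alternative p-values concentrate near 0. The height
#' \eqn{H_B} of the last bin therefore estimates the null density:
#' \eqn{\hat\pi_0 = \min(1, H_B \cdot B / m)}.
#'
#' @inheritParams scottBinCount
#' @param breaks positive integer bin count, or \code{"scott"} (default) for
#'   Scott's normal reference rule via \code{\link{scottBinCount}}.
#' @return a \code{\linkS4class{Pi0Estimate}} recording the bin count and
#'   last-bin height.
#' @examples
#' pi0Value(pi0LastHist(seq(0.05, 0.95, by = 0.1), breaks = 10))  # 1
#' @export
pi0LastHist <- function(pset, breaks = "scott") {
  pset <- .asPValueSet(pset)
  p <- pset@values
  m <- length(p)
  if (m < 2) stop("at least 2 p-values are required", call. = FALSE)
  B <- if (identical(breaks, "scott")) scottBinCount(pset)
       else as.integer(breaks)
  if (is.na(B) || B < 1) stop("bin count must be >= 1", call. = FALSE)
  HB <- .binCounts(p, B)[B]
  new("Pi0Estimate", value = min(1, HB * B / m), method = "last.hist",
      bins = B, lastBinHeight = as.numeric(HB), lambda = numeric(0))
}

#' Storey's smoothed-lambda pi0 estimator
#'
#' For each lambda in the grid computes the tail-count estimate
#' \eqn{\hat\pi_0(\lambda) = \#\{p_i > \lambda\} / (m (1 - \lambda))},
#' smooths the curve with a natural cubic smoothing spline (3 effective
#' degrees of freedom), and returns the smoothed value at the largest
#' lambda, capped to [0, 1]. A single-lambda grid returns the raw estimate;
#' grids of length 2-3 (too short for the spline) also return the raw
#' estimate at the largest lambda.
#'
#' @inheritParams scottBinCount
#' @param lambdaGrid strictly increasing values in (0, 1); default
#'   \code{seq(0.05, 0.95, by = 0.05)}.
#' @return a \code{\linkS4class{Pi0Estimate}} recording the grid.
#' @examples
#' pi0Value(pi0Storey(c(0.1, 0.2, 0.6, 0.8), lambdaGrid = 0.5))  # 1
#' @export
pi0Storey <- function(pset, lambdaGrid = seq(0.05, 0.95, by = 0.05)) {
  pset <- .asPValueSet(pset)
  p <- pset@values
  m <- length(p)
  if (m < 2) stop("at least 2 p-values are required", call. = FALSE)
  lam <- as.numeric(lambdaGrid)
  if (!length(lam)) stop("lambda grid must be non-empty", call. = FALSE)
  if (any(lam <= 0 | lam >= 1))
    stop("all lambda values must lie in (0, 1)", call. = FALSE)
  if (is.unsorted(lam, strictly = TRUE))
    stop("lambda grid must be strictly increasing", call. = FALSE)
  hat <- vapply(lam, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
  est <- if (length(lam) >= 4L) {
    fit <- stats::smooth.spline(lam, hat, df = 3)
    stats::predict(fit, x = max(lam))$y
  } else {
    hat[length(hat)]
  }
  new("Pi0Estimate", value = min(1, max(0, est)), method = "storey",
      bins = NA_integer_, lastBinHeight = NA_real_, lambda = lam)
}

#' Pounds-Cheng pi0 estimator
#'
#' \eqn{\hat\pi_0 = \min(1, 2 \bar p)}: under the uniform null the mean
#' p-value is 1/2, so twice the observed mean estimates the null fraction.
#'
#' @inheritParams scottBinCount
#' @return a \code{\linkS4class{Pi0Estimate}}.
#' @examples
#' pi0Value(pi0Pounds(c(0.1, 0.3)))  # 0.4
#' @export
pi0Pounds <- function(pset) {
  pset <- .asPValueSet(pset)
  new("Pi0Estimate", value = min(1, 2 * mean(pset@values)),
      method = "pounds", bins = NA_integer_, lastBinHeight = NA_real_,
      lambda = numeric(0))
}

#' Estimate the null proportion pi0
#'
#' Dispatches to the configured estimator. \code{"set.pi0"} (the default)
#' returns the supplied fixed value unchanged, ignoring the data — the
#' conservative default \code{setPi0 = 1} assumes every feature is null.
#'
#' @inheritParams scottBinCount
#' @param estimMethod one of \code{"set.pi0"} (default), \code{"last.hist"},
#'   \code{"storey"}, \code{"pounds"}.
#' @param setPi0 fixed value in [0, 1] for \code{"set.pi0"}; default 1.
#' @param histBreaks bin count or \code{"scott"} for \code{"last.hist"}.
#' @param lambdaGrid grid for \code{"storey"}.
#' @param naRm remove NA p-values (default TRUE) before estimation.
#' @return a \code{\linkS4class{Pi0Estimate}}; extract the number with
#'   \code{\link{pi0Value}}.
#' @examples
#' pi0Value(getPi0(runif(100), estimMethod = "set.pi0", setPi0 = 0.8))  # 0.8
#' @export
getPi0 <- function(pset, estimMethod = "set.pi0", setPi0 = 1,
                   histBreaks = "scott",
                   lambdaGrid = seq(0.05, 0.95, by = 0.05), naRm = TRUE) {
  if (length(estimMethod) != 1L ||
      !estimMethod %in% c("set.pi0", "last.hist", "storey", "pounds"))
    stop("unknown pi0 estimation method '", paste(estimMethod, collapse = ","),
         "'; options are set.pi0, last.hist, storey, pounds", call. = FALSE)
  pset <- .asPValueSet(pset, naPolicy = if (naRm) "remove" else "fail")
  switch(estimMethod,
    set.pi0 = {
      if (length(setPi0) != 1L || is.na(setPi0) || setPi0 < 0 || setPi0 > 1)
        stop("setPi0 must be a single value in [0, 1]", call. = FALSE)
      new("Pi0Estimate", value = setPi0, method = "set.pi0",
          bins = NA_integer_, lastBinHeight = NA_real_, lambda = numeric(0))
    },
    last.hist = pi0LastHist(pset, breaks = histBreaks),
    storey    = pi0Storey(pset, lambdaGrid = lambdaGrid),
    pounds    = pi0Pounds(pset))
}

#' @describeIn getPi0 the numeric pi0 value of an estimate.
#' @param object a \code{Pi0Estimate}.
#' @export
setMethod("pi0Value", "Pi0Estimate", function(object) object@value)

setMethod("show", "Pi0Estimate", function(object) {
  cat("Pi0Estimate:", format(object@value), paste0("(", object@method, ")"),
      "\n")
  if (!is.na(object@bins))
    cat("  bins:", object@bins, " last bin height:", object@lastBinHeight,
        "\n")
  if (length(object@lambda))
    cat("  lambda grid:", length(object@lambda), "values in [",
        min(object@lambda), ",", max(object@lambda), "]\n")
  invisible(NULL)
})
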