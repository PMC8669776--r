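#' Benjamini-Yekutieli correction factor c(m)
#'
#' The dependence correction scaling the BH criterion: the harmonic sum
#' \eqn{c(m) = \sum_{j=1}^{m} 1/j}, valid under arbitrary (flexible
#' positive) dependence. The same harmonic sum is used for
#' \code{byCorr = "negative"} — the most conservative published choice; pass
#' a custom value through the \code{cm} hook of \code{\link{fdrEstimate}} /
#' \code{\link{adjustPValues}} to override.
#'
#' @param m positive integer, the number of features.
#' @param byCorr \code{"positive"} (default) or \code{"negative"}.
#' @return the correction factor, a number >= 1.
#' @examples
#' cBY(2)  # 1.5
#' @export
cBY <- function(m, byCorr = c("positive", "negative")) {
  byCorr <- match.arg(byCorr)
  if (length(m) != 1L || is.na(m) || m < 1)
    stop("m must be a single integer >= 1", call. = FALSE)
  sum(1 / seq_len(as.integer(m)))
}

#' Per-feature FDR estimates
#'
#' Inverts the chosen control procedure into a per-feature estimate of the
#' false discovery rate. No step-up/step-down smoothing is applied at this
#' stage — that smoothing belongs to the adjusted p-values used for control,
#' not to FDR estimation — so the result need not be monotone in raw-p rank.
#'
#' Before capping at 1, the estimates are, with \eqn{m} features and
#' \eqn{r_i = rank(p_i)}:
#' \describe{
#'   \item{BH}{\eqn{p_i \cdot m / r_i \cdot \pi_0}}
#'   \item{BY}{\eqn{p_i \cdot m \cdot c(m) / r_i \cdot \pi_0}}
#'   \item{Bon}{\eqn{p_i \cdot m \cdot \pi_0}}
#'   \item{Sidak}{\eqn{(1 - (1 - p_i)^m) \cdot \pi_0}}
#'   \item{Holm, Hoch}{\eqn{p_i \cdot (m + 1 - r_i) \cdot \pi_0}}
#' }
#'
#' @param pset a \code{\linkS4class{PValueSet}} or numeric vector.
#' @param method adjustment method token: \code{"BH"} (default),
#'   \code{"BY"}, \code{"Bon"}, \code{"Sidak"}, \code{"Holm"},
#'   \code{"Hoch"}.
#' @param pi0 null proportion in [0, 1] multiplying the estimate; default 1
#'   (the conservative choice).
#' @param byCorr BY correlation variant; see \code{\link{cBY}}.
#' @param cm optional numeric overriding the BY correction factor.
#' @return numeric vector of FDR estimates in [0, 1], input order.
#' @examples
#' fdrEstimate(c(0.005, 0.049, 0.050, 0.051, 0.700))
#' @export
fdrEstimate <- function(pset, method = "BH", pi0 = 1,
                        byCorr = c("positive", "negative"), cm = NULL) {
  method <- .matchMethod(method)
  byCorr <- match.arg(byCorr)
  if (length(pi0) != 1L || is.na(pi0) || pi0 < 0 || pi0 > 1)
    stop("pi0 must be a single value in [0, 1]", call. = FALSE)
  pset <- .asPValueSet(pset)
  p <- pset@values
  m <- length(p)
  r <- rankPValues(pset)
  raw <- switch(method,
    BH    = p * m / r,
    BY    = p * m * (if (is.null(cm)) cBY(m, byCorr) else cm) / r,
    Bon   = p * m,
    Sidak = 1 - (1 - p)^m,
    Holm  = ,
    Hoch  = p * (m + 1 - r))
  pmin(1, raw * pi0)
}

#' Multiplicity-adjusted p-values
#'
#' Adjusted p-values for FDR/FWER control: the smallest threshold gamma at
#' which each feature would be selected by the method's procedure. Step
#' smoothing is applied where the method has one (step-up for BH, BY,
#' Hochberg; step-down for Holm), so the result is monotone in raw-p rank.
#' Unlike the FDR estimates, no pi0 term enters.
#'
#' @inheritParams fdrEstimate
#' @return numeric vector of adjusted p-values in [0, 1], input order.
#' @examples
#' adjustPValues(c(0.005, 0.049, 0.050, 0.051, 0.700))
#' @export
adjustPValues <- function(pset, method = "BH",
                          byCorr = c("positive", "negative"), cm = NULL) {
  method <- .matchMethod(method)
  byCorr <- match.arg(byCorr)
  pset <- .asPValueSet(pset)
  p <- pset@values
  m <- length(p)
  if (method == "Bon")   return(pmin(1, p * m))
  if (method == "Sidak") return(pmin(1, 1 - (1 - p)^m))
  o <- .resolvedOrder(pset)
  ps <- p[o]
  i <- seq_len(m)
  adjSorted <- switch(method,
    BH   = rev(cummin(rev(ps * m / i))),
    BY   = rev(cummin(rev(ps * m *
             (if (is.null(cm)) cBY(m, byCorr) else cm) / i))),
    Holm = cummax(ps * (m + 1 - i)),
    Hoch = rev(cummin(rev(ps * (m + 1 - i)))))
  out <- numeric(m)
  out[o] <- pmin(1, adjSorted)
  out
}

#' Step-up / step-down rejection set on raw p-values
#'
#' Runs the method's threshold search directly on the ordered raw p-values,
#' without going through adjusted p-values: for step-up methods (BH, BY,
#' Hochberg) the largest index k with \eqn{p_{(k)}} under the method's
#' criterion line is found and features of rank 1..k are flagged; Holm steps
#' down; Bonferroni and Sidak compare each p-value to a fixed cutoff. This
#' search is the procedures' original form and serves as an independent
#' cross-check of \code{\link{adjustPValues}}: the flags coincide with
#' \code{adjustPValues(...) <= gamma}.
#'
#' @inheritParams fdrEstimate
#' @param gamma rejection threshold in (0, 1).
#' @return list with \code{k}, the number of features selected, and
#'   \code{reject}, a logical vector in input order.
#' @examples
#' stepRejection(c(0.005, 0.049, 0.050, 0.051, 0.700), gamma = 0.05)$k
#' @export
stepRejection <- function(pset, gamma, method = "BH",
                          byCorr = c("positive", "negative"), cm = NULL) {
  method <- .matchMethod(method)
  byCorr <- match.arg(byCorr)
  if (length(gamma) != 1L || is.na(gamma) || gamma <= 0 || gamma >= 1)
    stop("gamma must be a single value in (0, 1)", call. = FALSE)
  pset <- .asPValueSet(pset)
  p <- pset@values
  m <- length(p)
  o <- .resolvedOrder(pset)
  ps <- p[o]
  i <- seq_len(m)
  crit <- switch(method,
    BH    = gamma * i / m,
    BY    = gamma * i / (m * (if (is.null(cm)) cBY(m, byCorr) else cm)),
    Holm  = ,
    Hoch  = gamma / (m + 1 - i),
    Bon   = rep(gamma / m, m),
    Sidak = rep(1 - (1 - gamma)^(1 / m), m))
  selSorted <- logical(m)
  if (method %in% c("BH", "BY", "Hoch")) {
    ok <- which(ps <= crit)
    k <- if (length(ok)) max(ok) else 0L
    if (k) selSorted[seq_len(k)] <- TRUE
  } else if (method == "Holm") {
    fail <- which(ps > crit)
    k <- if (length(fail)) min(fail) - 1L else m
    if (k) selSorted[seq_len(k)] <- TRUE
  } else {
    selSorted <- ps <= crit
    k <- sum(selSorted)
  }
  reject <- logical(m)
  reject[o] <- selSorted
  list(k = as.integer(k), reject = reject)
}

#' Compute FDR estimates and adjusted p-values from raw p-values
#'
#' The package's main entry point. Resolves the null proportion pi0 (fixed
#' value or estimated from the data), computes per-feature FDR estimates and
#' multiplicity-adjusted p-values for the chosen method, derives rejection
#' decisions by comparing the adjusted p-values to the threshold, and
#' optionally attaches Z-values and the univariate Gaussian lower bound on
#' the FDR.
#'
#' @param p numeric vector of raw p-values (NA allowed; see \code{naRm}) or
#'   a \code{\linkS4class{PValueSet}}.
#' @param adjustMethod one of \code{"BH"}, \code{"BY"}, \code{"Bon"},
#'   \code{"Sidak"}, \code{"Holm"}, \code{"Hoch"}.
#' @param threshold rejection threshold gamma in [0, 1]; default 0.05.
#' @param byCorr BY correlation variant; default \code{"positive"}.
#' @param estimMethod pi0 estimation method passed to \code{\link{getPi0}};
#'   default \code{"set.pi0"}.
#' @param setPi0 fixed pi0 for \code{estimMethod = "set.pi0"}; default 1.
#' @param histBreaks histogram bin count or \code{"scott"} for pi0
#'   estimation.
#' @param lambdaGrid lambda grid for the Storey estimator.
#' @param zvalues either a sidedness string (\code{"two.sided"},
#'   \code{"greater"}, \code{"less"}) used to derive Z-values from the
#'   p-values, or a numeric vector of Z-values. A supplied numeric vector
#'   must be consistent with the p-values under the two-sided transform
#'   (checked to within 1e-3).
#' @param defaultOdds prior odds pi1/pi0 for the lower bound; default 1.
#' @param lowerBound logical; attach the per-feature Gaussian lower bound on
#'   the FDR? Default TRUE.
#' @param tiesMethod,tieSeed tie handling; see \code{\link{PValueSet}}.
#' @param naRm remove NA p-values (default TRUE) or fail on them.
#' @param sortResults logical; order the result by increasing FDR estimate.
#' @param justFdr logical; return only the numeric FDR vector.
#' @return a \code{\linkS4class{FDRResult}}, or a numeric vector when
#'   \code{justFdr = TRUE}.
#' @examples
#' res <- pFDR(c(0.005, 0.049, 0.050, 0.051, 0.700))
#' fdrs(res)
#' adjustedPValues(res)
#' @export
pFDR <- function(p, adjustMethod = "BH", threshold = 0.05,
                 byCorr = c("positive", "negative"),
                 estimMethod = "set.pi0", setPi0 = 1, histBreaks = "scott",
                 lambdaGrid = seq(0.05, 0.95, by = 0.05),
                 zvalues = "two.sided", defaultOdds = 1, lowerBound = TRUE,
                 tiesMethod = "random", tieSeed = NULL, naRm = TRUE,
                 sortResults = FALSE, justFdr = FALSE) {
  adjustMethod <- .matchMethod(adjustMethod)
  byCorr <- match.arg(byCorr)
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0 ||
      threshold > 1)
    stop("threshold must be a single value in [0, 1]", call. = FALSE)
  pset <- .asPValueSet(p, naPolicy = if (naRm) "remove" else "fail",
                       tiesMethod = tiesMethod, tieSeed = tieSeed)
  raw <- pset@values
  m <- length(raw)

  pi0est <- getPi0(pset, estimMethod = estimMethod, setPi0 = setPi0,
                   histBreaks = histBreaks, lambdaGrid = lambdaGrid)
  pi0 <- pi0Value(pi0est)

  fdr <- fdrEstimate(pset, method = adjustMethod, pi0 = pi0,
                     byCorr = byCorr)
  if (justFdr) return(fdr)
  adj <- adjustPValues(pset, method = adjustMethod, byCorr = byCorr)

  if (is.character(zvalues)) {
    side <- match.arg(zvalues, c("two.sided", "greater", "less"))
    z <- pToZ(raw, side)
  } else {
    z <- as.numeric(zvalues)
    if (length(z) != m)
      stop("zvalues vector must match the number of retained p-values",
           call. = FALSE)
    side <- "two.sided"
    if (any(abs(zToP(z, side) - raw) > 1e-3))
      stop("supplied Z-values are inconsistent with the p-values under the ",
           "two-sided transform", call. = FALSE)
  }
  lb <- if (lowerBound) fdrLowerBound(raw, sidedness = side,
                                      odds = defaultOdds) else numeric(0)

  feature <- seq_len(m)
  if (sortResults) {
    ord <- order(fdr)
    feature <- feature[ord]; raw <- raw[ord]; z <- z[ord]
    fdr <- fdr[ord]; adj <- adj[ord]
    if (length(lb)) lb <- lb[ord]
  }
  new("FDRResult", feature = as.integer(feature), rawP = raw, zvalues = z,
      fdr = fdr, adjustedP = adj, lowerBound = lb,
      reject = ifelse(adj <= threshold, "Reject.H0", "FTR.H0"),
      pi0 = pi0, pi0Method = pi0est@method, threshold = threshold,
      method = adjustMethod, byCorr = byCorr)
}

#' @describeIn pFDR FDR estimates stored in a result.
#' @param object an \code{FDRResult}.
#' @export
setMethod("fdrs", "FDRResult", function(object) object@fdr)

#' @describeIn pFDR adjusted p-values stored in a result.
#' @export
setMethod("adjustedPValues", "FDRResult", function(object) object@adjustedP)

#' @describeIn pFDR raw p-values stored in a result.
#' @export
setMethod("pvalues", "FDRResult", function(object, ...) object@rawP)

#' @describeIn pFDR number of features in a result.
#' @export
setMethod("nFeatures", "FDRResult", function(object) length(object@rawP))

#' @describeIn pFDR rejection labels (\code{Reject.H0} / \code{FTR.H0}).
#' @export
setMethod("rejectFlags", "FDRResult", function(object) object@reject)

#' @describeIn pFDR pi0 value used in the FDR estimates.
#' @export
setMethod("pi0Value", "FDRResult", function(object) object@pi0)

#' @describeIn pFDR adjustment method token.
#' @export
setMethod("adjustMethod", "FDRResult", function(object) object@method)

#' @describeIn pFDR rejection threshold gamma.
#' @export
setMethod("threshold", "FDRResult", function(object) object@threshold)

#' @describeIn pFDR per-feature Gaussian lower bound (empty if not computed).
#' @export
setMethod("lowerBoundFDR", "FDRResult", function(object, ...) object@lowerBound)

#' Coerce an FDRResult to a data.frame
#'
#' One row per feature with columns \code{feature}, \code{raw_p},
#' \code{adjusted_p}, \code{fdr}, optionally \code{lower_bound_fdr}, and
#' \code{reject}.
#'
#' @param x an \code{FDRResult}.
#' @param row.names,optional ignored (S3 signature).
#' @param ... ignored.
#' @export
as.data.frame.FDRResult <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  df <- data.frame(feature = x@feature, raw_p = x@rawP,
                   adjusted_p = x@adjustedP, fdr = x@fdr,
                   stringsAsFactors = FALSE)
  if (length(x@lowerBound)) df$lower_bound_fdr <- x@lowerBound
  df$reject <- x@reject
  df
}

setMethod("show", "FDRResult", function(object) {
  m <- length(object@rawP)
  cat("FDRResult:", object@method, "adjustment,", m, "feature(s)\n")
  cat("  threshold:", object@threshold, " pi0:", format(object@pi0),
      paste0("(", object@pi0Method, ")\n"))
  cat("  rejections:", sum(object@reject == "Reject.H0"), "of", m, "\n")
  df <- as.data.frame(object)
  print(utils::head(df, 10L), digits = 4)
  if (m > 10L) cat("  ...", m - 10L, "more row(s)\n")
  invisible(NULL)
})
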