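#' @import methods
NULL

#' PValueSet: a validated vector of raw p-values
#'
#' Container for a vector of raw (unadjusted) p-values together with the
#' missing-value policy that was applied and the tie-handling configuration
#' used whenever ranks are derived from the set. All downstream operations
#' (FDR estimates, adjusted p-values, pi0 estimation) consume a
#' \code{PValueSet} so that the number of features \code{m}, the tie policy
#' and the retained values are fixed in one place.
#'
#' @slot values numeric vector of retained p-values, all in [0, 1], no NAs.
#' @slot tiesMethod character; one of \code{"first"}, \code{"last"},
#'   \code{"average"}, \code{"min"}, \code{"max"}, \code{"random"}. Governs
#'   \code{\link{rankPValues}}.
#' @slot tieSeed integer seed driving the \code{"random"} ties method. When
#'   the user supplies none, an internal fixed seed is used so that results
#'   are reproducible by default.
#'
#' @seealso \code{\link{PValueSet}} (constructor), \code{\link{rankPValues}}
#' @export
setClass("PValueSet",
  representation(values = "numeric", tiesMethod = "character",
                 tieSeed = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (anyNA(object@values))
      msg <- c(msg, "retained p-values must not contain NA")
    bad <- which(object@values < 0 | object@values > 1)
    if (length(bad))
      msg <- c(msg, paste0("p-values outside [0, 1] at position(s): ",
                           paste(utils::head(bad, 5L), collapse = ", ")))
    if (length(object@tiesMethod) != 1L ||
        !object@tiesMethod %in% c("first", "last", "average", "min", "max",
                                  "random"))
      msg <- c(msg, "tiesMethod must be one of first/last/average/min/max/random")
    if (length(object@tieSeed) != 1L || is.na(object@tieSeed))
      msg <- c(msg, "tieSeed must be a single non-missing integer")
    if (length(msg)) msg else TRUE
  })

#' FDRResult: per-feature FDR estimates and adjusted p-values
#'
#' The result object assembled by \code{\link{pFDR}}. Per-feature vectors are
#' parallel and kept in input order unless the result was sorted by the FDR
#' column, in which case \code{feature} records the original indices.
#'
#' An essential property of this container is that \code{fdr} (the
#' per-feature FDR estimates) and \code{adjustedP} (the adjusted p-values for
#' FDR/FWER control) are distinct quantities: adjusted p-values are monotone
#' in raw-p rank by construction, FDR estimates need not be.
#'
#' @slot feature integer; original 1-based feature indices.
#' @slot rawP numeric; the raw p-values.
#' @slot zvalues numeric; Z-values matching \code{rawP} under the sidedness
#'   used (length 0 when not computed).
#' @slot fdr numeric in [0, 1]; per-feature FDR estimates (no step smoothing,
#'   multiplied by pi0, capped at 1).
#' @slot adjustedP numeric in [0, 1]; multiplicity-adjusted p-values (step
#'   smoothing applied where the method has one; no pi0 term).
#' @slot lowerBound numeric; univariate Gaussian lower bound on the FDR
#'   (length 0 when not computed).
#' @slot reject character; \code{"Reject.H0"} where \code{adjustedP <=
#'   threshold}, else \code{"FTR.H0"}.
#' @slot pi0 numeric; the null-proportion value used in the FDR estimates.
#' @slot pi0Method character; how \code{pi0} was obtained.
#' @slot threshold numeric; the rejection threshold gamma.
#' @slot method character; adjustment method token (BH, BY, Bon, Sidak,
#'   Holm, Hoch).
#' @slot byCorr character; BY correlation variant ("positive"/"negative").
#'
#' @export
setClass("FDRResult",
  representation(feature = "integer", rawP = "numeric", zvalues = "numeric",
                 fdr = "numeric", adjustedP = "numeric",
                 lowerBound = "numeric", reject = "character",
                 pi0 = "numeric", pi0Method = "character",
                 threshold = "numeric", method = "character",
                 byCorr = "character"),
  validity = function(object) {
    m <- length(object@rawP)
    msg <- character(0)
    if (length(object@fdr) != m || length(object@adjustedP) != m ||
        length(object@reject) != m || length(object@feature) != m)
      msg <- c(msg, "per-feature slots must have equal length")
    if (length(object@zvalues) && length(object@zvalues) != m)
      msg <- c(msg, "zvalues must be empty or match the number of features")
    if (length(object@lowerBound) && length(object@lowerBound) != m)
      msg <- c(msg, "lowerBound must be empty or match the number of features")
    if (any(object@fdr < 0 | object@fdr > 1))
      msg <- c(msg, "fdr values must lie in [0, 1]")
    if (any(object@adjustedP < 0 | object@adjustedP > 1))
      msg <- c(msg, "adjusted p-values must lie in [0, 1]")
    if (!all(object@reject %in% c("Reject.H0", "FTR.H0")))
      msg <- c(msg, "reject labels must be Reject.H0 or FTR.H0")
    want <- ifelse(object@adjustedP <= object@threshold, "Reject.H0", "FTR.H0")
    if (!identical(object@reject, want))
      msg <- c(msg, "reject labels must equal adjustedP <= threshold")
    if (object@pi0 < 0 || object@pi0 > 1)
      msg <- c(msg, "pi0 must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Pi0Estimate: an estimated null proportion
#'
#' @slot value numeric in [0, 1]; the (capped) estimate of the null
#'   proportion pi0.
#' @slot method character; the estimator label (\code{"set.pi0"},
#'   \code{"last.hist"}, \code{"storey"}, \code{"pounds"}).
#' @slot bins integer; the histogram bin count B used (NA when not
#'   applicable).
#' @slot lastBinHeight numeric; the count H_B in the bin adjacent to 1 (NA
#'   when not applicable).
#' @slot lambda numeric; the lambda grid used by the Storey estimator
#'   (length 0 otherwise).
#'
#' @export
setClass("Pi0Estimate",
  representation(value = "numeric", method = "character", bins = "integer",
                 lastBinHeight = "numeric", lambda = "numeric"),
  validity = function(object) {
    if (length(object@value) != 1L || is.na(object@value) ||
        object@value < 0 || object@value > 1)
      return("pi0 value must be a single number in [0, 1]")
    TRUE
  })

#' TwoGroupModel: Gaussian two-group mixture on the Z scale
#'
#' Each feature's Z-value is drawn from the null density f0 with probability
#' pi0 or from the alternative density f1 with probability 1 - pi0. Both
#' components are Gaussian; the theoretical null is N(0, 1) by default.
#'
#' @slot pi0 numeric in [0, 1]; the null (mixing) proportion.
#' @slot nullMean,nullSd numeric; parameters of f0 (defaults 0 and 1).
#' @slot altMean,altSd numeric; parameters of f1.
#'
#' @seealso \code{\link{mixtureDensity}}, \code{\link{fdrRegion}}
#' @export
setClass("TwoGroupModel",
  representation(pi0 = "numeric", nullMean = "numeric", nullSd = "numeric",
                 altMean = "numeric", altSd = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (object@pi0 < 0 || object@pi0 > 1)
      msg <- c(msg, "pi0 must lie in [0, 1]")
    if (object@nullSd <= 0 || object@altSd <= 0)
      msg <- c(msg, "component standard deviations must be positive")
    if (length(msg)) msg else TRUE
  })

#' SimulationBatch: labeled synthetic p-values
#'
#' Replicated two-group p-value data with known null/alternative labels, as
#' produced by \code{\link{simulatePValues}}. The label layout is identical
#' across replicates: the first \code{round(m * pi0True)} features of each
#' replicate are null.
#'
#' @slot pvalues numeric matrix, replicates in rows, features in columns.
#' @slot isNull logical vector of length \code{m}; TRUE for null features.
#' @slot spec list; the generating specification (m, pi0True, altKind,
#'   altParams, reps, seed, sidedness).
#'
#' @export
setClass("SimulationBatch",
  representation(pvalues = "matrix", isNull = "logical", spec = "list"),
  validity = function(object) {
    msg <- character(0)
    if (ncol(object@pvalues) != length(object@isNull))
      msg <- c(msg, "isNull must have one entry per feature column")
    if (any(object@pvalues < 0 | object@pvalues > 1))
      msg <- c(msg, "all simulated p-values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })
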