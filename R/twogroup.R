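#' Construct a Gaussian two-group mixture model
#'
#' Z-values arise from the null density f0 = N(nullMean, nullSd^2) with
#' probability pi0 and from the alternative f1 = N(altMean, altSd^2) with
#' probability 1 - pi0. The theoretical null is the standard normal.
#'
#' @param pi0 null proportion in [0, 1].
#' @param nullMean,nullSd f0 parameters; defaults 0 and 1.
#' @param altMean,altSd f1 parameters; defaults 2 and 1.
#' @return a \code{\linkS4class{TwoGroupModel}}.
#' @examples
#' TwoGroupModel(pi0 = 0.8)
#' @export
TwoGroupModel <- function(pi0, nullMean = 0, nullSd = 1, altMean = 2,
                          altSd = 1) {
  new("TwoGroupModel", pi0 = pi0, nullMean = nullMean, nullSd = nullSd,
      altMean = altMean, altSd = altSd)
}

#' @describeIn TwoGroupModel the null proportion of a model.
#' @param object a \code{TwoGroupModel}.
#' @export
setMethod("pi0Value", "TwoGroupModel", function(object) object@pi0)

setMethod("show", "TwoGroupModel", function(object) {
  cat("TwoGroupModel: pi0 =", object@pi0, "\n")
  cat("  f0 ~ N(", object@nullMean, ",", object@nullSd, "^2)  f1 ~ N(",
      object@altMean, ",", object@altSd, "^2)\n")
  invisible(NULL)
})

#' Mixture density of a two-group model
#'
#' \eqn{f(z) = \pi_0 f_0(z) + (1 - \pi_0) f_1(z)}.
#'
#' @param model a \code{\linkS4class{TwoGroupModel}}.
#' @param z numeric vector of evaluation points.
#' @return numeric vector of density values.
#' @examples
#' mixtureDensity(TwoGroupModel(0.8), 0)  # ~0.33
#' @export
mixtureDensity <- function(model, z) {
  stopifnot(is(model, "TwoGroupModel"))
  model@pi0 * stats::dnorm(z, model@nullMean, model@nullSd) +
    (1 - model@pi0) * stats::dnorm(z, model@altMean, model@altSd)
}

# Internal: component probability of a tail region under N(mean, sd).
.tailProb <- function(cutoff, tail, mean, sd) {
  switch(tail,
    upper = stats::pnorm(cutoff, mean, sd, lower.tail = FALSE),
    lower = stats::pnorm(cutoff, mean, sd),
    two.sided = stats::pnorm(-abs(cutoff), mean, sd) +
      stats::pnorm(abs(cutoff), mean, sd, lower.tail = FALSE))
}

#' Empirical-Bayes FDR of a tail rejection region
#'
#' For a rejection region Z (a one-sided half-line beyond \code{cutoff}, or
#' the two-tailed region beyond |cutoff|), applies Bayes' theorem to the
#' two-group model: \eqn{FDR(Z) = \Pr(null \mid z \in Z) = \pi_0 F_0(Z) /
#' F(Z)} with mixture probability \eqn{F(Z) = \pi_0 F_0(Z) + \pi_1 F_1(Z)}.
#'
#' @param model a \code{\linkS4class{TwoGroupModel}}.
#' @param cutoff numeric cutoff defining the region.
#' @param tail \code{"upper"} (z >= cutoff, default), \code{"lower"}
#'   (z <= cutoff), or \code{"two.sided"} (|z| >= |cutoff|).
#' @return the FDR of the region, a probability.
#' @examples
#' fdrRegion(TwoGroupModel(0.8), 1.96)  # ~0.162
#' @export
fdrRegion <- function(model, cutoff, tail = c("upper", "lower", "two.sided")) {
  stopifnot(is(model, "TwoGroupModel"))
  tail <- match.arg(tail)
  F0 <- .tailProb(cutoff, tail, model@nullMean, model@nullSd)
  F1 <- .tailProb(cutoff, tail, model@altMean, model@altSd)
  Fmix <- model@pi0 * F0 + (1 - model@pi0) * F1
  if (Fmix <= 0)
    stop("rejection region has zero mass under the mixture; FDR undefined",
         call. = FALSE)
  model@pi0 * F0 / Fmix
}
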