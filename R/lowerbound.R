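#' Univariate Gaussian lower bound on the FDR
#'
#' A benchmark lower bound on the posterior probability of the null
#' hypothesis — effectively the FDR of a single finding — under a Gaussian
#' model: \eqn{(1 + \exp(z^2/2) \cdot odds)^{-1}}, where \code{odds} is the
#' prior odds \eqn{\pi_1/\pi_0} (default 1). The bound uses only the
#' feature's own Z-value, borrows no strength across features, and so also
#' applies when a single test is performed. At z = 0 and odds 1 the bound is
#' exactly 1/2; it decreases strictly in |z| and in the odds.
#'
#' \code{fdrLowerBound} accepts p-values (transformed to Z through
#' \code{\link{pToZ}} under the stated sidedness); \code{fdrLowerBoundZ}
#' accepts Z-values directly.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param z numeric vector of finite Z-values.
#' @param sidedness sidedness of the p-values; default \code{"two.sided"}.
#' @param odds prior odds pi1/pi0, a positive number; default 1.
#' @return numeric vector of lower bounds in (0, 1/(1 + odds)].
#' @examples
#' fdrLowerBoundZ(1.951)        # ~0.13
#' fdrLowerBound(0.700)         # ~0.481
#' fdrLowerBoundZ(0)            # exactly 0.5
#' @export
fdrLowerBoundZ <- function(z, odds = 1) {
  if (length(odds) != 1L || is.na(odds) || odds <= 0)
    stop("odds must be a single positive number", call. = FALSE)
  if (any(!is.finite(z)))
    stop("Z-values must be finite", call. = FALSE)
  1 / (1 + exp(z^2 / 2) * odds)
}

#' @rdname fdrLowerBoundZ
#' @export
fdrLowerBound <- function(p, sidedness = c("two.sided", "greater", "less"),
                          odds = 1) {
  sidedness <- match.arg(sidedness)
  fdrLowerBoundZ(pToZ(p, sidedness), odds = odds)
}
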