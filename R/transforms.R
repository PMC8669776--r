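#' Convert p-values to Z-values
#'
#' Maps raw p-values to Z-values through standard normal quantiles under a
#' stated sidedness: \code{two.sided} gives \eqn{z = \Phi^{-1}(1 - p/2)},
#' \code{greater} gives \eqn{\Phi^{-1}(1 - p)}, \code{less} gives
#' \eqn{\Phi^{-1}(p)}. These Z-values are working quantities for the
#' two-group model, not reconstructions of the original test statistics.
#'
#' p = 0 is clamped to the smallest positive double before the quantile
#' transform so the result stays finite.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param sidedness \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"}.
#' @return numeric vector of Z-values.
#' @examples
#' pToZ(0.005)            # 2.807
#' pToZ(1)                # 0
#' @seealso \code{\link{zToP}}
#' @export
pToZ <- function(p, sidedness = c("two.sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  bad <- which(!is.na(p) & (p < 0 | p > 1))
  if (length(bad))
    stop("p-values outside [0, 1] at position(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  pc <- pmax(p, .Machine$double.xmin)
  # upper-tail quantile form keeps the clamped p = 0 case finite
  switch(sidedness,
         two.sided = stats::qnorm(pc / 2, lower.tail = FALSE),
         greater   = stats::qnorm(pc, lower.tail = FALSE),
         less      = stats::qnorm(pc))
}

#' Convert Z-values to p-values
#'
#' Exact inverse of \code{\link{pToZ}} for the same sidedness.
#'
#' @param z numeric vector of finite Z-values.
#' @inheritParams pToZ
#' @return numeric vector of p-values in [0, 1].
#' @examples
#' zToP(2.807)   # ~0.005
#' @export
zToP <- function(z, sidedness = c("two.sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  if (any(!is.finite(z)))
    stop("Z-values must be finite", call. = FALSE)
  switch(sidedness,
         two.sided = pmin(1, 2 * stats::pnorm(z, lower.tail = FALSE)),
         greater   = stats::pnorm(z, lower.tail = FALSE),
         less      = stats::pnorm(z))
}

#' Rank p-values with configurable tie handling
#'
#' Ranks ascending p-values using the tie policy stored in the set. With
#' \code{tiesMethod = "random"} tied blocks receive a random permutation of
#' their rank range, driven by the set's tie seed, so repeated calls on the
#' same set agree. For tie methods that resolve ties to distinct integers
#' (first, last, random) the result is a permutation of 1..m.
#'
#' @param pset a \code{\linkS4class{PValueSet}}.
#' @return numeric rank vector (integer-valued except for
#'   \code{tiesMethod = "average"}).
#' @examples
#' rankPValues(PValueSet(c(0.2, 0.1, 0.3)))
#' @export
rankPValues <- function(pset) {
  pset <- .asPValueSet(pset)
  p <- pset@values
  if (!length(p)) stop("empty p-value set", call. = FALSE)
  if (pset@tiesMethod == "random")
    .withSeed(pset@tieSeed, rank(p, ties.method = "random"))
  else
    rank(p, ties.method = pset@tiesMethod)
}

# Internal: ordering of features consistent with rankPValues. When the ranks
# are a permutation of 1..m the order inverts them exactly, so tie resolution
# is shared between rank-based formulas and step procedures; otherwise
# (average/min/max ranks) ties are ordered by position, which step procedures
# are insensitive to.
.resolvedOrder <- function(pset) {
  r <- rankPValues(pset)
  m <- length(r)
  if (setequal(r, seq_len(m))) order(r) else order(pset@values)
}
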