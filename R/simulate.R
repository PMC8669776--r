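#' Simulate two-group p-values with known labels
#'
#' Generates replicated p-value data under the two-group model: null
#' features draw p ~ Uniform(0, 1); alternative features draw either
#' p ~ Uniform(0, u) (\code{altKind = "uniform_small"}, a sharply skewed
#' alternative) or a Z-value from N(mean, sd) converted to a p-value under
#' the stated sidedness (\code{altKind = "gaussian_shift"}). The first
#' \code{round(m * pi0True)} features of every replicate are null; the rest
#' are alternatives. Output is bit-reproducible for a fixed seed.
#'
#' @param m features per replicate.
#' @param pi0True true null proportion in [0, 1].
#' @param altKind \code{"uniform_small"} (default) or
#'   \code{"gaussian_shift"}.
#' @param altParams list of alternative parameters: \code{u} (default 0.01)
#'   for \code{uniform_small}; \code{mean} (default 2) and \code{sd}
#'   (default 1) for \code{gaussian_shift}.
#' @param reps number of replicates; default 1.
#' @param seed integer RNG seed; default 1.
#' @param sidedness sidedness used to convert shifted Z-values to p-values;
#'   default \code{"two.sided"}.
#' @return a \code{\linkS4class{SimulationBatch}}.
#' @examples
#' batch <- simulatePValues(m = 100, pi0True = 0.8, reps = 2, seed = 1)
#' dim(pvalues(batch))
#' @export
simulatePValues <- function(m, pi0True,
                            altKind = c("uniform_small", "gaussian_shift"),
                            altParams = list(), reps = 1, seed = 1,
                            sidedness = c("two.sided", "greater", "less")) {
  altKind <- match.arg(altKind)
  sidedness <- match.arg(sidedness)
  if (length(m) != 1L || m < 1) stop("m must be >= 1", call. = FALSE)
  if (pi0True < 0 || pi0True > 1)
    stop("pi0True must lie in [0, 1]", call. = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  m <- as.integer(m); reps <- as.integer(reps)
  n0 <- as.integer(round(m * pi0True))
  n1 <- m - n0
  drawAlt <- switch(altKind,
    uniform_small = {
      u <- if (is.null(altParams$u)) 0.01 else altParams$u
      if (u <= 0 || u > 1) stop("u must lie in (0, 1]", call. = FALSE)
      function(n) stats::runif(n, min = 0, max = u)
    },
    gaussian_shift = {
      mu <- if (is.null(altParams$mean)) 2 else altParams$mean
      sdv <- if (is.null(altParams$sd)) 1 else altParams$sd
      if (sdv <= 0) stop("sd must be positive", call. = FALSE)
      function(n) {
        z <- stats::rnorm(n, mean = mu, sd = sdv)
        if (sidedness == "two.sided") zToP(abs(z), "two.sided")
        else zToP(z, sidedness)
      }
    })
  mat <- .withSeed(as.integer(seed), {
    t(vapply(seq_len(reps),
             function(r) c(stats::runif(n0), drawAlt(n1)),
             numeric(m)))
  })
  dimnames(mat) <- NULL
  new("SimulationBatch", pvalues = mat,
      isNull = c(rep(TRUE, n0), rep(FALSE, n1)),
      spec = list(m = m, pi0True = pi0True, altKind = altKind,
                  altParams = altParams, reps = reps,
                  seed = as.integer(seed), sidedness = sidedness))
}

#' @describeIn simulatePValues the reps x m p-value matrix of a batch.
#' @param object a \code{SimulationBatch}.
#' @export
setMethod("pvalues", "SimulationBatch", function(object, ...) object@pvalues)

#' @describeIn simulatePValues logical null labels (length m).
#' @export
setMethod("nullLabels", "SimulationBatch", function(object) object@isNull)

#' @describeIn simulatePValues features per replicate.
#' @export
setMethod("nFeatures", "SimulationBatch",
          function(object) ncol(object@pvalues))

setMethod("show", "SimulationBatch", function(object) {
  s <- object@spec
  cat("SimulationBatch:", s$reps, "replicate(s) x", s$m, "feature(s)\n")
  cat("  pi0True:", s$pi0True, " alternative:", s$altKind, "\n")
  invisible(NULL)
})

#' Benchmark pi0 estimators over a grid of true null proportions
#'
#' For every true pi0 in the grid, simulates \code{reps} replicates of
#' \code{m} two-group p-values and applies each configured pi0 estimator,
#' reporting the mean estimate and the mean squared error against the truth.
#' Derived seeds stay below 2^31.
#'
#' @param pi0Grid numeric vector of true null proportions.
#' @param altKind,altParams,sidedness alternative specification; see
#'   \code{\link{simulatePValues}}.
#' @param methods character vector of estimators: any of \code{"last.hist"},
#'   \code{"storey"}, \code{"pounds"}, \code{"set.pi0"}.
#' @param setPi0 value used by the \code{"set.pi0"} estimator.
#' @param reps replicates per grid point; default 200.
#' @param m features per replicate; default 1000.
#' @param seed base RNG seed; default 1.
#' @return data.frame with columns \code{method}, \code{pi0_true},
#'   \code{alt_kind}, \code{mean_estimate}, \code{mse}.
#' @examples
#' evaluatePi0Methods(0.8, methods = "pounds", reps = 5, m = 200)
#' @export
evaluatePi0Methods <- function(pi0Grid, altKind = "uniform_small",
                               altParams = list(),
                               methods = c("last.hist", "storey", "pounds"),
                               setPi0 = 1, reps = 200, m = 1000, seed = 1,
                               sidedness = "two.sided") {
  rows <- list()
  for (g in seq_along(pi0Grid)) {
    truth <- pi0Grid[g]
    batch <- simulatePValues(m = m, pi0True = truth, altKind = altKind,
                             altParams = altParams, reps = reps,
                             seed = (as.integer(seed) + 7919L * g) %% .Machine$integer.max,
                             sidedness = sidedness)
    pv <- batch@pvalues
    for (meth in methods) {
      est <- vapply(seq_len(nrow(pv)), function(r) {
        pi0Value(getPi0(pv[r, ], estimMethod = meth, setPi0 = setPi0))
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        method = meth, pi0_true = truth, alt_kind = altKind,
        mean_estimate = mean(est), mse = mean((est - truth)^2),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Realized FDR and power of a control procedure by simulation
#'
#' Runs \code{\link{stepRejection}} on every replicate of a labeled batch
#' and reports the realized false discovery proportion (false selections /
#' selections, defined as 0 when nothing is selected) and power (true
#' selections / alternatives) per replicate, plus their means and the
#' Monte-Carlo standard error of the mean FDR.
#'
#' @param batch a \code{\linkS4class{SimulationBatch}}.
#' @param method adjustment method token; default \code{"BH"}.
#' @param gamma rejection threshold; default 0.05. \code{gamma = 0} selects
#'   nothing (FDR 0 in every replicate).
#' @param byCorr BY correlation variant.
#' @return list with \code{perRep} (data.frame: rep, selections,
#'   false_selections, fdr, power), \code{meanFDR}, \code{meanPower},
#'   \code{seFDR}.
#' @examples
#' b <- simulatePValues(100, 0.8, reps = 10, seed = 1)
#' empiricalFDR(b)$meanFDR
#' @export
empiricalFDR <- function(batch, method = "BH", gamma = 0.05,
                         byCorr = "positive") {
  stopifnot(is(batch, "SimulationBatch"))
  isNull <- batch@isNull
  nAlt <- sum(!isNull)
  pv <- batch@pvalues
  reps <- nrow(pv)
  sel <- fp <- tp <- integer(reps)
  if (gamma > 0) {
    for (r in seq_len(reps)) {
      flags <- stepRejection(pv[r, ], gamma = gamma, method = method,
                             byCorr = byCorr)$reject
      sel[r] <- sum(flags)
      fp[r] <- sum(flags & isNull)
      tp[r] <- sum(flags & !isNull)
    }
  }
  fdr <- fp / pmax(1L, sel)
  power <- if (nAlt) tp / nAlt else rep(0, reps)
  list(perRep = data.frame(rep = seq_len(reps), selections = sel,
                           false_selections = fp, fdr = fdr, power = power,
                           stringsAsFactors = FALSE),
       meanFDR = mean(fdr), meanPower = mean(power),
       seFDR = stats::sd(fdr) / sqrt(reps))
}
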