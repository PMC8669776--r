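#' Plot FDR estimates, adjusted p-values and raw p-values
#'
#' Draws the three per-feature series of an \code{\linkS4class{FDRResult}}
#' against either the raw-p rank or the Z-value, with the raw-p step-up
#' rejection line (gamma * i / m, rank axis only) and the horizontal
#' adjusted-p threshold line. Every series and line can be suppressed.
#'
#' @param result an \code{\linkS4class{FDRResult}}.
#' @param xAxis \code{"rank"} (default) or \code{"zvalues"} (requires the
#'   result to carry Z-values).
#' @param rawPValues,adjPValues,fdrPoints plot the respective point series?
#'   All default TRUE.
#' @param sigLine plot the raw-p rejection line gamma * i / m (rank axis
#'   only)? Default TRUE.
#' @param adjSigLine plot the horizontal threshold line? Default TRUE.
#' @param gamma threshold used for the lines; defaults to the result's.
#' @param xlim,ylim axis limits; \code{ylim} defaults to c(0, 1).
#' @param legendWhere legend position; defaults to \code{"topleft"} for the
#'   rank axis and \code{"topright"} for the Z axis.
#' @param main plot title.
#' @param pchAdjP,pchRawP,pchFdr plotting symbols; defaults 17, 20, 20.
#' @param col colors for (FDR, adjusted p, raw p); a single color is
#'   recycled. Default \code{c("dodgerblue", "firebrick2", "black")}.
#' @param file optional path; when given, a PNG device is opened, the plot
#'   written there and the device closed.
#' @return invisibly, a list of the plotted series (each with x and y), for
#'   programmatic inspection.
#' @export
plotFDRResult <- function(result, xAxis = c("rank", "zvalues"),
                          rawPValues = TRUE, adjPValues = TRUE,
                          fdrPoints = TRUE, sigLine = TRUE,
                          adjSigLine = TRUE, gamma = NULL, xlim = NULL,
                          ylim = c(0, 1), legendWhere = NULL, main = NULL,
                          pchAdjP = 17, pchRawP = 20, pchFdr = 20,
                          col = c("dodgerblue", "firebrick2", "black"),
                          file = NULL) {
  stopifnot(is(result, "FDRResult"))
  xAxis <- match.arg(xAxis)
  m <- length(result@rawP)
  if (!m) stop("empty result", call. = FALSE)
  if (length(col) == 1L) col <- rep(col, 3L)
  if (is.null(gamma)) gamma <- result@threshold
  if (xAxis == "zvalues") {
    if (!length(result@zvalues))
      stop("result carries no Z-values; recompute with a sidedness or ",
           "Z-vector", call. = FALSE)
    x <- result@zvalues
    xlab <- "Z-value"
    if (is.null(legendWhere)) legendWhere <- "topright"
  } else {
    x <- rank(result@rawP, ties.method = "first")
    xlab <- "Rank of raw p-value"
    if (is.null(legendWhere)) legendWhere <- "topleft"
  }
  if (is.null(xlim)) xlim <- range(x)
  if (is.null(main))
    main <- paste0(result@method, " FDR estimates and adjusted p-values")
  series <- list()
  if (is.null(file)) file <- NULL
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = xlab,
                 ylab = "Probability", main = main)
  if (fdrPoints) {
    graphics::points(x, result@fdr, pch = pchFdr, col = col[1])
    series$fdr <- list(x = x, y = result@fdr)
  }
  if (adjPValues) {
    graphics::points(x, result@adjustedP, pch = pchAdjP, col = col[2])
    series$adjusted_p <- list(x = x, y = result@adjustedP)
  }
  if (rawPValues) {
    graphics::points(x, result@rawP, pch = pchRawP, col = col[3])
    series$raw_p <- list(x = x, y = result@rawP)
  }
  if (sigLine && xAxis == "rank") {
    graphics::abline(a = 0, b = gamma / m, lty = 2, col = col[3])
    series$sig_line <- list(slope = gamma / m)
  }
  if (adjSigLine) {
    graphics::abline(h = gamma, lty = 3, col = col[1])
    series$adj_sig_line <- list(h = gamma)
  }
  lab <- c(if (fdrPoints) "FDR estimate",
           if (adjPValues) "Adjusted p-value",
           if (rawPValues) "Raw p-value")
  pchs <- c(if (fdrPoints) pchFdr, if (adjPValues) pchAdjP,
            if (rawPValues) pchRawP)
  cols <- c(if (fdrPoints) col[1], if (adjPValues) col[2],
            if (rawPValues) col[3])
  if (length(lab))
    graphics::legend(legendWhere, legend = lab, pch = pchs, col = cols,
                     bty = "n")
  invisible(series)
}

#' Diagnostic plots for pi0 estimation
#'
#' Draws a density-scale histogram of the p-values with a horizontal line at
#' the height of the bin adjacent to 1 (the Last Histogram Height null
#' level, which on the density scale equals the uncapped pi0 estimate
#' H_B * B / m). When a \code{\linkS4class{TwoGroupModel}} is supplied, a
#' second panel shows a density histogram of the Z-values overlaid with the
#' null, alternative and mixture densities.
#'
#' @param pset a \code{\linkS4class{PValueSet}} or numeric vector (m >= 2).
#' @param model optional \code{TwoGroupModel} for the Z-scale panel.
#' @param breaks bin count or \code{"scott"}; see \code{\link{pi0LastHist}}.
#' @param zvalues optional numeric Z-values for the model panel; derived
#'   from the p-values via \code{\link{pToZ}} when absent.
#' @param sidedness sidedness for the p-to-Z transform; default
#'   \code{"two.sided"}.
#' @param file optional PNG output path.
#' @return invisibly, a list with the bin count \code{B}, last-bin height
#'   \code{HB} and the density-scale line level.
#' @export
plotPi0Diagnostics <- function(pset, model = NULL, breaks = "scott",
                               zvalues = NULL, sidedness = "two.sided",
                               file = NULL) {
  pset <- .asPValueSet(pset)
  p <- pset@values
  m <- length(p)
  if (m < 2) stop("at least 2 p-values are required", call. = FALSE)
  est <- pi0LastHist(pset, breaks = breaks)
  B <- est@bins
  HB <- est@lastBinHeight
  level <- HB * B / m  # density of the last bin
  if (!is.null(file)) {
    grDevices::png(file, width = if (is.null(model)) 800 else 1200,
                   height = 600)
    on.exit(grDevices::dev.off())
  }
  if (!is.null(model)) {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old), add = TRUE, after = FALSE)
  }
  graphics::hist(p, breaks = seq(0, 1, length.out = B + 1), freq = FALSE,
                 main = "Raw p-values", xlab = "p-value",
                 col = "grey90")
  graphics::abline(h = level, col = "firebrick2", lwd = 2)
  if (!is.null(model)) {
    z <- if (is.null(zvalues)) pToZ(p, sidedness) else zvalues
    graphics::hist(z, breaks = "Scott", freq = FALSE, main = "Z-values",
                   xlab = "Z-value", col = "grey90")
    grid <- seq(min(z) - 1, max(z) + 1, length.out = 400)
    graphics::lines(grid, stats::dnorm(grid, model@nullMean, model@nullSd),
                    col = "dodgerblue", lwd = 2)
    graphics::lines(grid, stats::dnorm(grid, model@altMean, model@altSd),
                    col = "firebrick2", lwd = 2)
    graphics::lines(grid, mixtureDensity(model, grid), col = "black",
                    lwd = 2)
    graphics::legend("topright",
                     legend = c("null f0", "alternative f1", "mixture"),
                     col = c("dodgerblue", "firebrick2", "black"), lwd = 2,
                     bty = "n")
  }
  invisible(list(B = B, HB = HB, level = level))
}
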