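## Size-number relationship fits for chromocenters: reciprocal count versus
## square-root area (linear), count versus area (power law on log-log axes),
## individual-size histogram (exponential), centromere count versus
## chromocenter area (linear and exponential), and the control-versus-treated
## cohort comparison. All fits are ordinary least squares; R-squared is
## always reported on the fitted (possibly transformed) scale.

.olsFitResult <- function(x, y, model, details = list()) {
  if (length(x) < 3) stop("need at least 3 points")
  if (diff(range(x)) == 0) stop("zero-variance predictor")
  fit <- lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  r2v <- if (sst == 0) 0 else
    max(0, 1 - sum(stats::residuals(fit)^2) / sst)
  cf <- coef(fit)
  new("FitResult", model = model,
      coefficients = c(intercept = unname(cf[1]), slope = unname(cf[2])),
      exponent = if (model == "power") unname(cf[2]) else NA_real_,
      r2 = r2v, nPoints = length(x),
      residuals = unname(stats::residuals(fit)), details = details)
}

#' Linear fit of reciprocal chromocenter count on square-root mean area
#'
#' Per-cell regression of 1/n on sqrt(mean chromocenter area): under
#' conservation of the total chromocenter amount, cells with fewer, larger
#' chromocenters line up on a positive linear trend with this
#' parameterization.
#'
#' @param cells data.frame from [summarizeCells()] (needs `n_pads` and
#'   `sqrt_mean_area`); cells with zero chromocenters are excluded.
#' @return a [FitResult-class] (`model = "linear"`).
#' @export
fitReciprocalSqrt <- function(cells) {
  ok <- cells$n_pads >= 1 & is.finite(cells$sqrt_mean_area)
  x <- cells$sqrt_mean_area[ok]
  y <- 1 / cells$n_pads[ok]
  .olsFitResult(x, y, "linear", details = list(excluded = sum(!ok)))
}

#' Power-law fit on log-log axes
#'
#' OLS of log10(y) on log10(x); the exponent is the log-log slope.
#' Non-positive values are excluded (count logged) before fitting. The
#' exponent is invariant under multiplying x or y by a positive constant.
#'
#' @param x,y positive numeric vectors (e.g. per-cell mean chromocenter
#'   area and chromocenter count).
#' @return a [FitResult-class] (`model = "power"`).
#' @examples
#' f <- fitPowerLaw(1:20, 5 / (1:20))
#' exponent(f)  # -1
#' @export
fitPowerLaw <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (sum(ok) < 3)
    stop("fewer than 3 positive points after filtering (",
         sum(!ok), " excluded)")
  .olsFitResult(log10(x[ok]), log10(y[ok]), "power",
                details = list(excluded = sum(!ok), logBase = 10))
}

#' Exponential fit of the individual chromocenter size distribution
#'
#' Histograms the individual areas in equal-width bins up to `areaCap`
#' (default 6 um^2, covering the bulk of the size spectrum), then fits OLS
#' of log(count) on bin centre over the non-empty bins. A decreasing size
#' spectrum yields a negative rate (the slope, in natural-log units).
#'
#' @param areas individual chromocenter areas (um^2), at least 30.
#' @param nBins number of equal-width bins.
#' @param areaCap upper area bound of the histogram (um^2).
#' @return a [FitResult-class] (`model = "exponential"`); details carry the
#'   bin centres and counts.
#' @export
fitExponential <- function(areas, nBins = 12, areaCap = 6) {
  areas <- areas[is.finite(areas) & areas > 0]
  if (length(areas) < 30) stop("need at least 30 chromocenter areas")
  areas <- areas[areas <= areaCap]
  breaks <- seq(0, areaCap, length.out = nBins + 1)
  cnt <- tabulate(findInterval(areas, breaks, rightmost.closed = TRUE),
                  nbins = nBins)
  ctr <- (breaks[-1] + breaks[-(nBins + 1)]) / 2
  keep <- cnt > 0
  if (sum(keep) < 3) stop("fewer than 3 non-empty bins")
  .olsFitResult(ctr[keep], log(cnt[keep]), "exponential",
                details = list(binCenters = ctr[keep], counts = cnt[keep],
                               areaCap = areaCap))
}

#' Centromere clustering fits: count versus chromocenter area
#'
#' Both a linear fit (count on area) and an exponential fit (log count on
#' area) are returned so their R-squared can be compared; chromocenters
#' with zero counted centromeres are excluded from both (log undefined).
#' When all counts are equal the exponential fit is degenerate and flagged.
#'
#' @param pads data.frame (from `records(pads)`) with `area_um2` and
#'   `centromere_count`; at least 10 chromocenters with count >= 1.
#' @return list with elements `linear` and `exponential`
#'   ([FitResult-class] each).
#' @export
fitCentromereClustering <- function(pads) {
  ok <- is.finite(pads$centromere_count) & pads$centromere_count >= 1 &
    is.finite(pads$area_um2)
  if (sum(ok) < 10)
    stop("need at least 10 chromocenters with counted centromeres")
  a <- pads$area_um2[ok]; k <- pads$centromere_count[ok]
  lin <- .olsFitResult(a, k, "linear", details = list(excluded = sum(!ok)))
  if (diff(range(k)) == 0) {
    expo <- new("FitResult", model = "exponential",
                coefficients = c(intercept = log(k[1]), slope = 0),
                exponent = NA_real_, r2 = 0, nPoints = length(k),
                residuals = rep(0, length(k)),
                details = list(flag = "degenerate: all counts equal"))
  } else {
    expo <- .olsFitResult(a, log(k), "exponential",
                          details = list(excluded = sum(!ok)))
  }
  list(linear = lin, exponential = expo)
}

#' Compare chromocenter organisation between two conditions
#'
#' Per cohort: the reciprocal-sqrt fit and the count-versus-mean-area
#' power-law fit; medians of the per-cell mean chromocenter area; a Welch
#' test on per-cell mean areas; and boxplot-ready five-number summaries.
#' A treated cohort that has lost the scale-free organisation shows up as
#' an R-squared drop relative to control.
#'
#' @param controlCells,treatedCells data.frames from [summarizeCells()].
#' @return list: `control`, `treated` (each: `fits`, `median_mean_area`,
#'   `boxplot`), `test` (Welch on per-cell mean areas), `r2_drop`
#'   (control power-law R2 minus treated).
#' @export
compareConditions <- function(controlCells, treatedCells) {
  stopifnot(nrow(controlCells) > 0, nrow(treatedCells) > 0)
  one <- function(cells) {
    ok <- cells$n_pads >= 1 & is.finite(cells$mean_area_um2)
    fits <- list(
      reciprocal_sqrt = tryCatch(fitReciprocalSqrt(cells),
                                 error = function(e) NULL),
      power = tryCatch(fitPowerLaw(cells$mean_area_um2[ok],
                                   cells$n_pads[ok]),
                       error = function(e) NULL))
    list(fits = fits,
         median_mean_area = median(cells$mean_area_um2[ok]),
         mean_areas = cells$mean_area_um2[ok],
         boxplot = grDevices::boxplot.stats(cells$mean_area_um2[ok])$stats)
  }
  ctl <- one(controlCells); trt <- one(treatedCells)
  tst <- shiftTest(ctl$mean_areas, trt$mean_areas)
  r2drop <- if (!is.null(ctl$fits$power) && !is.null(trt$fits$power))
    r2(ctl$fits$power) - r2(trt$fits$power) else NA_real_
  list(control = ctl[c("fits", "median_mean_area", "boxplot")],
       treated = trt[c("fits", "median_mean_area", "boxplot")],
       test = tst, r2_drop = r2drop)
}
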