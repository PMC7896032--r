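## Acridine-orange DNA structural test: the red/green (R/G) index per
## nucleus and its population-level normalized shift statistics. Higher R/G
## indicates a more unfolded DNA conformation.

#' R/G DNA-conformation index of one nucleus
#'
#' Integrated fluorescence intensity of the red and green planes over the
#' nucleus mask; the index is their ratio IFI_red / IFI_green. A zero green
#' IFI makes the ratio undefined: the measurement is flagged invalid. No
#' background subtraction is applied by default; an optional constant
#' offset can be subtracted from both planes.
#'
#' @param image a [NucleusImage-class] with `red` and `green` channels.
#' @param mask logical matrix (nucleus pixels).
#' @param offset constant background offset subtracted from every pixel of
#'   both planes before integration (default 0).
#' @param nucleusId label stored with the measurement.
#' @return one-row data.frame: `nucleus_id`, `ifi_red`, `ifi_green`,
#'   `rg_raw`, `valid`.
#' @examples
#' img <- NucleusImage(list(red = matrix(2, 4, 4), green = matrix(1, 4, 4)),
#'                     pxPerUm = 1)
#' rgIndex(img, matrix(TRUE, 4, 4))$rg_raw  # 2
#' @export
rgIndex <- function(image, mask, offset = 0, nucleusId = 1L) {
  stopifnot(is(image, "NucleusImage"), is.matrix(mask),
            all(dim(mask) == dim(image)))
  if (!all(c("red", "green") %in% channelNames(image)))
    stop("red and green planes required")
  sel <- mask != 0
  if (!any(sel)) stop("empty mask")
  r <- sum(pmax(channel(image, "red")[sel] - offset, 0))
  g <- sum(pmax(channel(image, "green")[sel] - offset, 0))
  valid <- g > 0
  data.frame(nucleus_id = nucleusId, ifi_red = r, ifi_green = g,
             rg_raw = if (valid) r / g else NA_real_, valid = valid)
}

#' R/G index for every nucleus of a segmented field
#'
#' @param image a [NucleusImage-class] with `red` and `green` channels.
#' @param nuclei a [NucleusSet-class].
#' @param offset see [rgIndex()].
#' @return data.frame, one row per nucleus.
#' @export
rgIndexSet <- function(image, nuclei, offset = 0) {
  stopifnot(is(nuclei, "NucleusSet"))
  nlab <- labelMatrix(nuclei)
  ids <- records(nuclei)$nucleus_id
  do.call(rbind, lapply(ids, function(i)
    rgIndex(image, nlab == i, offset = offset, nucleusId = i)))
}

#' Normalize R/G measurements to the control-group mean
#'
#' Every raw ratio is divided by the arithmetic mean of the control group's
#' raw ratios, so the control mean becomes exactly 1. Scale-invariant:
#' multiplying all raw values by a constant leaves the normalized values
#' unchanged.
#'
#' @param treated numeric vector of raw R/G values (or a data.frame from
#'   [rgIndexSet()], whose valid `rg_raw` column is used).
#' @param control same, for the control (starving) population.
#' @return list with `treated`, `control` (normalized values) and `summary`
#'   (data.frame: group, mean, sd, n).
#' @export
normalizePopulation <- function(treated, control) {
  tv <- .rgValues(treated); cv <- .rgValues(control)
  if (length(cv) == 0) stop("empty control group")
  m <- mean(cv)
  if (m <= 0) stop("non-positive control mean")
  tn <- tv / m; cn <- cv / m
  list(treated = tn, control = cn,
       summary = data.frame(
         group = c("control", "treated"),
         mean = c(mean(cn), mean(tn)),
         sd = c(sd(cn), sd(tn)),
         n = c(length(cn), length(tn))))
}

.rgValues <- function(x) {
  if (is.data.frame(x)) x <- x$rg_raw[x$valid]
  x <- x[is.finite(x)]
  x
}

#' Welch test for a population R/G shift
#'
#' Two-tailed Welch t-test on (normalized) per-nucleus values. Degenerate
#' zero-variance groups short-circuit: p = 1 when the means are equal,
#' otherwise p is reported as below machine epsilon with a flag.
#'
#' @param groupA,groupB numeric vectors (each length >= 2).
#' @return data.frame: `statistic`, `df`, `p`, `flag`.
#' @export
shiftTest <- function(groupA, groupB) {
  stopifnot(length(groupA) >= 2, length(groupB) >= 2)
  if (sd(groupA) == 0 && sd(groupB) == 0) {
    if (mean(groupA) == mean(groupB))
      return(data.frame(statistic = 0, df = NA_real_, p = 1, flag = ""))
    return(data.frame(statistic = Inf, df = NA_real_,
                      p = .Machine$double.xmin, flag = "zero_variance"))
  }
  tt <- t.test(groupA, groupB, var.equal = FALSE)
  data.frame(statistic = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, flag = "")
}

#' Detect bimodal structure in normalized R/G values
#'
#' Reports (does not test) whether a population histogram separates into two
#' peaks: local maxima of a kernel density estimate whose modes are more
#' than `minSeparation` pooled standard deviations apart.
#'
#' @param values numeric vector of normalized R/G values.
#' @param minSeparation mode separation (in SD units) to call bimodality.
#' @return list: `bimodal` (logical), `modes` (numeric positions of the two
#'   strongest density peaks, or one if unimodal).
#' @export
detectBimodality <- function(values, minSeparation = 2) {
  stopifnot(length(values) >= 10)
  d <- density(values)
  y <- d$y
  peak <- which(diff(sign(diff(y))) == -2) + 1
  if (length(peak) < 2)
    return(list(bimodal = FALSE, modes = d$x[which.max(y)]))
  peak <- peak[order(y[peak], decreasing = TRUE)][1:2]
  modes <- sort(d$x[peak])
  # pooled within-mode SD: split at the midpoint between the two modes
  cut <- mean(modes)
  lo <- values[values <= cut]; hi <- values[values > cut]
  pooled <- if (length(lo) >= 2 && length(hi) >= 2)
    sqrt(((length(lo) - 1) * stats::var(lo) +
          (length(hi) - 1) * stats::var(hi)) /
         (length(lo) + length(hi) - 2))
  else sd(values)
  list(bimodal = diff(modes) > minSeparation * pooled, modes = modes)
}
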