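## Per-cell measures derived from segmentations: DNA-content gating,
## euchromatin heterogeneity, and the per-cell chromocenter summary.

#' Gate cells by integrated DAPI fluorescence intensity
#'
#' The modal IFI of the population (taller peak of a kernel density
#' estimate) anchors the diploid 2C gate: cells inside
#' `mode * [1 - w, 1 + w]` are 2C, above it S-G2, below it preapoptotic.
#' Optionally, low-IFI cells are called preapoptotic only when their mean
#' chromocenter area is in the population's top quartile (preapoptotic
#' cells aggregate their chromocenters); otherwise they stay unassigned.
#'
#' @param nuclei a [NucleusSet-class] (pooled over fields).
#' @param modeWindow half-width w of the 2C window (default 0.25).
#' @param minCells minimum records for mode estimation; below it all gates
#'   stay `"unassigned"` with a warning.
#' @param padArea optional numeric vector (mean chromocenter area per
#'   nucleus, aligned with the records) enabling the aggregation criterion
#'   for the preapoptotic gate.
#' @return the [NucleusSet-class] with gates filled; the log gains
#'   `gate_fractions` and `ifi_mode`.
#' @export
gateCells <- function(nuclei, modeWindow = 0.25, minCells = 20,
                      padArea = NULL) {
  stopifnot(is(nuclei, "NucleusSet"), modeWindow > 0, modeWindow < 1)
  tb <- records(nuclei)
  log <- processingLog(nuclei)
  if (nrow(tb) < minCells) {
    warning("too few cells (", nrow(tb), " < ", minCells,
            ") for mode estimation; all gates unassigned")
    tb$gate <- "unassigned"
    log$gate_fractions <- NULL
    return(new("NucleusSet", labels = labelMatrix(nuclei), table = tb,
               pxPerUm = pxPerUm(nuclei), log = log))
  }
  ifi <- tb$dapi_ifi
  if (diff(range(ifi)) == 0) {
    m <- ifi[1]
  } else {
    d <- density(ifi)
    m <- d$x[which.max(d$y)]
  }
  gate <- ifelse(ifi > m * (1 + modeWindow), "S-G2",
          ifelse(ifi < m * (1 - modeWindow), "preapoptotic", "2C"))
  if (!is.null(padArea)) {
    stopifnot(length(padArea) == nrow(tb))
    q3 <- quantile(padArea, 0.75, na.rm = TRUE)
    low <- gate == "preapoptotic"
    gate[low & (is.na(padArea) | padArea < q3)] <- "unassigned"
  }
  tb$gate <- gate
  log$ifi_mode <- m
  log$gate_fractions <- c(
    "2C" = mean(gate == "2C"), "S-G2" = mean(gate == "S-G2"),
    "preapoptotic" = mean(gate == "preapoptotic"),
    "unassigned" = mean(gate == "unassigned"))
  new("NucleusSet", labels = labelMatrix(nuclei), table = tb,
      pxPerUm = pxPerUm(nuclei), log = log)
}

#' Euchromatin heterogeneity of a nucleus
#'
#' Fraction of mask pixels whose intensity deviates by strictly more than
#' `tolerance` (default 10 percent) from the mean intensity over the mask.
#' Invariant under multiplying all intensities by a positive constant; a
#' uniformly zero field is defined as perfectly homogeneous (0).
#'
#' @param image a [NucleusImage-class].
#' @param mask logical matrix selecting the nucleus pixels.
#' @param tolerance relative deviation threshold (strict inequality).
#' @param channelName channel carrying the euchromatin stain (default
#'   `"green"`, H3K4me3).
#' @return fraction in [0, 1].
#' @examples
#' img <- NucleusImage(list(green = matrix(c(50, 150), 10, 10)), pxPerUm = 1)
#' heterogeneity(img, matrix(TRUE, 10, 10))  # every pixel deviates 50%
#' @export
heterogeneity <- function(image, mask, tolerance = 0.10,
                          channelName = "green") {
  stopifnot(is(image, "NucleusImage"), is.matrix(mask),
            all(dim(mask) == dim(image)), tolerance >= 0)
  v <- channel(image, channelName)[mask != 0]
  if (length(v) == 0) stop("empty mask")
  m <- mean(v)
  if (m == 0) {
    message("zero mean intensity over mask; heterogeneity defined as 0")
    return(0)
  }
  mean(abs(v - m) > tolerance * m)
}

#' Per-cell chromocenter summary
#'
#' Aggregates a nucleus' chromocenters into the quantities the size-number
#' analysis uses: count n, mean and total area, the square root of the mean
#' area (a proxy of chromocenter perimeter), and, when the image is given,
#' the euchromatin heterogeneity over the nucleus mask. Cells with zero
#' chromocenters get `NA` means and are flagged so fits can exclude them.
#'
#' @param nuclei a [NucleusSet-class].
#' @param pads a [PADSet-class] segmented from the same image(s).
#' @param image optional [NucleusImage-class] for the heterogeneity column.
#' @param tolerance heterogeneity tolerance (see [heterogeneity()]).
#' @return data.frame with columns `nucleus_id`, `n_pads`, `mean_area_um2`,
#'   `total_area_um2`, `sqrt_mean_area`, `heterogeneity`, `flag`.
#' @export
summarizeCells <- function(nuclei, pads, image = NULL, tolerance = 0.10) {
  stopifnot(is(nuclei, "NucleusSet"), is(pads, "PADSet"))
  ntb <- records(nuclei); ptb <- records(pads)
  het <- rep(NA_real_, nrow(ntb))
  if (!is.null(image)) {
    nlab <- labelMatrix(nuclei)
    for (i in seq_len(nrow(ntb)))
      het[i] <- heterogeneity(image, nlab == ntb$nucleus_id[i], tolerance)
  }
  out <- data.frame(nucleus_id = ntb$nucleus_id,
                    n_pads = 0L, mean_area_um2 = NA_real_,
                    total_area_um2 = 0, sqrt_mean_area = NA_real_,
                    heterogeneity = het, flag = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ntb))) {
    a <- ptb$area_um2[ptb$nucleus_id == ntb$nucleus_id[i]]
    if (length(a) == 0) { out$flag[i] <- "no_pads"; next }
    out$n_pads[i] <- length(a)
    out$mean_area_um2[i] <- mean(a)
    out$total_area_um2[i] <- sum(a)
    out$sqrt_mean_area[i] <- sqrt(mean(a))
  }
  out
}
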