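#' @import methods
#' @importFrom stats coef density lm median quantile rnorm runif sd setNames
#'   t.test pt p.adjust aggregate rbinom sample.int
#' @importFrom utils write.csv read.csv head
NULL

#' Multi-channel nucleus image
#'
#' Container for one registered field of view: a named list of same-shape
#' intensity rasters (matrices, row-major, pixel-centred coordinates) plus the
#' pixel-size calibration. Channel names carry the biological role, e.g.
#' `blue` (DAPI), `red` (H3K9me3 or AO red plane), `green` (CENPA, H3K4me3 or
#' AO green plane).
#'
#' @slot channels named list of numeric matrices, all the same dimension,
#'   intensities non-negative.
#' @slot pxPerUm pixels per micrometre (scalar, positive).
#' @slot fieldId character label of the field.
#' @export
setClass("NucleusImage",
  representation(channels = "list", pxPerUm = "numeric", fieldId = "character"))

setValidity("NucleusImage", function(object) {
  ch <- object@channels
  if (length(ch) == 0) return("at least one channel required")
  if (is.null(names(ch)) || anyDuplicated(names(ch)))
    return("channels must be uniquely named")
  if (!all(vapply(ch, is.matrix, logical(1))))
    return("each channel must be a matrix")
  dims <- vapply(ch, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all channels must share one dimension")
  if (any(vapply(ch, function(m) any(m < 0), logical(1))))
    return("intensities must be non-negative")
  if (length(object@pxPerUm) != 1 || !is.finite(object@pxPerUm) ||
      object@pxPerUm <= 0)
    return("pxPerUm must be a positive scalar")
  TRUE
})

#' Construct a NucleusImage
#'
#' @param channels named list of non-negative numeric matrices (same shape).
#' @param pxPerUm pixels per micrometre.
#' @param fieldId field label.
#' @return A [NucleusImage-class] object.
#' @examples
#' img <- NucleusImage(list(blue = matrix(1, 8, 8)), pxPerUm = 8)
#' channelNames(img)
#' @export
NucleusImage <- function(channels, pxPerUm, fieldId = "field1") {
  new("NucleusImage", channels = channels, pxPerUm = as.numeric(pxPerUm),
      fieldId = as.character(fieldId))
}

#' Segmented nuclei of one or more fields
#'
#' Holds the integer label raster (0 = background) and one record per nucleus:
#' `nucleus_id`, `area_px`, `area_um2`, `dapi_ifi` (integrated DAPI
#' fluorescence intensity over the mask), `gate` (one of `"2C"`, `"S-G2"`,
#' `"preapoptotic"`, `"unassigned"`) and `flag`.
#'
#' @slot labels integer matrix of nucleus labels.
#' @slot table data.frame of per-nucleus records.
#' @slot pxPerUm calibration used for area conversion.
#' @slot log named list: dropped-object counts, gate fractions, warnings.
#' @export
setClass("NucleusSet",
  representation(labels = "matrix", table = "data.frame",
                 pxPerUm = "numeric", log = "list"))

setValidity("NucleusSet", function(object) {
  tb <- object@table
  need <- c("nucleus_id", "area_px", "area_um2", "dapi_ifi", "gate")
  if (!all(need %in% names(tb)))
    return(paste("table must contain:", paste(need, collapse = ", ")))
  if (nrow(tb) > 0 && any(tb$area_px <= 0)) return("area_px must be positive")
  if (nrow(tb) > 0 && any(tb$dapi_ifi < 0)) return("dapi_ifi must be >= 0")
  TRUE
})

#' Segmented chromocenters (PADs)
#'
#' Label raster and per-PAD records: `pad_id`, `nucleus_id`, `area_px`,
#' `area_um2`, `centromere_count` (NA until [countCentromeres()] runs).
#' Every PAD mask is nested in its parent nucleus mask and PAD masks are
#' pairwise disjoint.
#'
#' @slot labels integer matrix of PAD labels.
#' @slot table data.frame of per-PAD records.
#' @slot pxPerUm calibration.
#' @slot log named list of counts (dropped small components etc.).
#' @export
setClass("PADSet",
  representation(labels = "matrix", table = "data.frame",
                 pxPerUm = "numeric", log = "list"))

setValidity("PADSet", function(object) {
  tb <- object@table
  need <- c("pad_id", "nucleus_id", "area_px", "area_um2", "centromere_count")
  if (!all(need %in% names(tb)))
    return(paste("table must contain:", paste(need, collapse = ", ")))
  if (nrow(tb) > 0 && any(tb$area_px <= 0)) return("area_px must be positive")
  cc <- tb$centromere_count
  if (nrow(tb) > 0 && any(!is.na(cc) & cc < 0))
    return("centromere_count must be >= 0")
  TRUE
})

#' Result of a size-number regression
#'
#' @slot model one of `"linear"`, `"power"`, `"exponential"`.
#' @slot coefficients named numeric: `intercept`, `slope` on the fitted scale.
#' @slot exponent for power-law fits, the log-log slope; `NA` otherwise.
#' @slot r2 coefficient of determination on the fitted (possibly transformed)
#'   scale.
#' @slot nPoints number of points entering the fit.
#' @slot residuals residuals on the fitted scale.
#' @slot details named list (e.g. excluded-point counts, bin centres, flags).
#' @export
setClass("FitResult",
  representation(model = "character", coefficients = "numeric",
                 exponent = "numeric", r2 = "numeric", nPoints = "integer",
                 residuals = "numeric", details = "list"))

setValidity("FitResult", function(object) {
  if (!object@model %in% c("linear", "power", "exponential"))
    return("model must be linear, power or exponential")
  if (!all(c("intercept", "slope") %in% names(object@coefficients)))
    return("coefficients must be named intercept, slope")
  if (is.finite(object@r2) && (object@r2 < -1e-9 || object@r2 > 1 + 1e-9))
    return("r2 out of [0, 1]")
  if (object@nPoints < 0) return("nPoints must be >= 0")
  TRUE
})
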