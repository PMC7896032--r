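#' Channel names of an image
#' @param x a [NucleusImage-class].
#' @return character vector of channel names.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Extract one channel raster
#' @param x a [NucleusImage-class].
#' @param name channel name.
#' @return numeric matrix.
#' @export
setGeneric("channel", function(x, name) standardGeneric("channel"))

#' Pixel calibration (pixels per micrometre)
#' @param x an object carrying a calibration.
#' @return numeric scalar.
#' @export
setGeneric("pxPerUm", function(x) standardGeneric("pxPerUm"))

#' Field identifier
#' @param x a [NucleusImage-class].
#' @return character scalar.
#' @export
setGeneric("fieldId", function(x) standardGeneric("fieldId"))

#' Per-object record table
#' @param x a [NucleusSet-class] or [PADSet-class].
#' @return data.frame with one row per segmented object.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' Integer label raster of a segmentation
#' @param x a [NucleusSet-class] or [PADSet-class].
#' @return integer matrix, 0 = background.
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' Processing log of a segmentation
#' @param x a [NucleusSet-class] or [PADSet-class].
#' @return named list of counts and messages.
#' @export
setGeneric("processingLog", function(x) standardGeneric("processingLog"))

#' Coefficient of determination of a fit
#' @param x a [FitResult-class].
#' @return numeric scalar on the fitted scale.
#' @export
setGeneric("r2", function(x) standardGeneric("r2"))

#' Power-law exponent of a fit
#' @param x a [FitResult-class].
#' @return numeric scalar (NA for non-power models).
#' @export
setGeneric("exponent", function(x) standardGeneric("exponent"))

#' Number of points used in a fit
#' @param x a [FitResult-class].
#' @return integer.
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))
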