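#' @describeIn NucleusImage channel names
#' @param x,name,object see generic.
#' @export
setMethod("channelNames", "NucleusImage", function(x) names(x@channels))

#' @describeIn NucleusImage extract one channel raster
#' @export
setMethod("channel", "NucleusImage", function(x, name) {
  if (!name %in% names(x@channels))
    stop("no channel named '", name, "' (have: ",
         paste(names(x@channels), collapse = ", "), ")")
  x@channels[[name]]
})

#' @describeIn NucleusImage pixel calibration
#' @export
setMethod("pxPerUm", "NucleusImage", function(x) x@pxPerUm)

#' @describeIn NucleusImage field label
#' @export
setMethod("fieldId", "NucleusImage", function(x) x@fieldId)

#' @describeIn NucleusImage raster dimension (rows, cols)
#' @export
setMethod("dim", "NucleusImage", function(x) dim(x@channels[[1]]))

setMethod("show", "NucleusImage", function(object) {
  d <- dim(object)
  cat("NucleusImage '", object@fieldId, "': ", d[1], " x ", d[2],
      " px, ", length(object@channels), " channel(s) [",
      paste(names(object@channels), collapse = ", "), "], ",
      format(object@pxPerUm), " px/um\n", sep = "")
})

#' @describeIn NucleusSet per-nucleus record table
#' @param x,object see generic.
#' @export
setMethod("records", "NucleusSet", function(x) x@table)

#' @describeIn NucleusSet label raster
#' @export
setMethod("labelMatrix", "NucleusSet", function(x) x@labels)

#' @describeIn NucleusSet calibration
#' @export
setMethod("pxPerUm", "NucleusSet", function(x) x@pxPerUm)

#' @describeIn NucleusSet processing log
#' @export
setMethod("processingLog", "NucleusSet", function(x) x@log)

setMethod("show", "NucleusSet", function(object) {
  cat("NucleusSet:", nrow(object@table), "nuclei")
  gt <- table(object@table$gate)
  if (nrow(object@table))
    cat(" (", paste(names(gt), gt, sep = "=", collapse = ", "), ")", sep = "")
  cat("\n")
})

#' @describeIn PADSet per-PAD record table
#' @param x,object see generic.
#' @export
setMethod("records", "PADSet", function(x) x@table)

#' @describeIn PADSet label raster
#' @export
setMethod("labelMatrix", "PADSet", function(x) x@labels)

#' @describeIn PADSet calibration
#' @export
setMethod("pxPerUm", "PADSet", function(x) x@pxPerUm)

#' @describeIn PADSet processing log
#' @export
setMethod("processingLog", "PADSet", function(x) x@log)

setMethod("show", "PADSet", function(object) {
  cat("PADSet:", nrow(object@table), "chromocenters in",
      length(unique(object@table$nucleus_id)), "nuclei\n")
})

#' @describeIn FitResult coefficient of determination
#' @param x,object see generic.
#' @export
setMethod("r2", "FitResult", function(x) x@r2)

#' @describeIn FitResult power-law exponent (log-log slope)
#' @export
setMethod("exponent", "FitResult", function(x) x@exponent)

#' @describeIn FitResult number of fitted points
#' @export
setMethod("nPoints", "FitResult", function(x) x@nPoints)

#' @describeIn FitResult fitted coefficients (intercept, slope)
#' @export
setMethod("coef", "FitResult", function(object) object@coefficients)

setMethod("show", "FitResult", function(object) {
  cat("FitResult [", object@model, "]: slope=",
      format(object@coefficients[["slope"]], digits = 4),
      ", intercept=", format(object@coefficients[["intercept"]], digits = 4),
      ", R2=", format(object@r2, digits = 3),
      ", n=", object@nPoints, "\n", sep = "")
  if (object@model == "power")
    cat("  exponent (log-log slope): ",
        format(object@exponent, digits = 4), "\n", sep = "")
})
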