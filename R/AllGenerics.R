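# Generics and accessor methods. Slots are never accessed with @ from user
# code; these accessors are the supported surface.

#' @export
setGeneric("imagePixels", function(x) standardGeneric("imagePixels"))
#' @export
setGeneric("mmPerPx", function(x) standardGeneric("mmPerPx"))
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))
#' @export
setGeneric("roiMode", function(x) standardGeneric("roiMode"))
#' @export
setGeneric("roiVertices", function(x) standardGeneric("roiVertices"))
#' @export
setGeneric("psiEstimate", function(x) standardGeneric("psiEstimate"))
#' @export
setGeneric("psiCI", function(x) standardGeneric("psiCI"))
#' @export
setGeneric("plateauLevel", function(x) standardGeneric("plateauLevel"))
#' @export
setGeneric("riseSlope", function(x) standardGeneric("riseSlope"))
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
#' @export
setGeneric("sseProfile", function(x) standardGeneric("sseProfile"))
#' @export
setGeneric("rasterValues", function(x) standardGeneric("rasterValues"))
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @export
setGeneric("cellCenters", function(x) standardGeneric("cellCenters"))

#' Accessors for ProfileImage
#' @param x a [ProfileImage-class] object.
#' @return `imagePixels`: the rows x cols x 3 pixel array; `mmPerPx`: the
#'   physical scale; `imageId`: the identifier.
#' @aliases imagePixels mmPerPx imageId
#' @export
setMethod("imagePixels", "ProfileImage", function(x) x@pixels)
#' @rdname imagePixels-ProfileImage-method
#' @export
setMethod("mmPerPx", "ProfileImage", function(x) x@mmPerPx)
#' @rdname imagePixels-ProfileImage-method
#' @export
setMethod("imageId", "ProfileImage", function(x) x@imageId)

#' Accessors for RegionOfInterest
#' @param x a [RegionOfInterest-class] object.
#' @aliases roiMode roiVertices
#' @export
setMethod("roiMode", "RegionOfInterest", function(x) x@mode)
#' @rdname roiMode-RegionOfInterest-method
#' @export
setMethod("roiVertices", "RegionOfInterest", function(x) x@vertices)

#' Accessors for PlateauFit
#'
#' @param x a [PlateauFit-class] object.
#' @return `psiEstimate`: breakpoint (m); `psiCI`: its confidence bounds;
#'   `plateauLevel`: background grey; `riseSlope`: grey per metre;
#'   `rSquared`, `isConverged`, `sseProfile`: diagnostics.
#' @aliases psiEstimate psiCI plateauLevel riseSlope rSquared isConverged
#'   sseProfile
#' @export
setMethod("psiEstimate", "PlateauFit", function(x) x@psi)
#' @rdname psiEstimate-PlateauFit-method
#' @export
setMethod("psiCI", "PlateauFit", function(x) x@psiCI)
#' @rdname psiEstimate-PlateauFit-method
#' @export
setMethod("plateauLevel", "PlateauFit", function(x) x@plateauLevel)
#' @rdname psiEstimate-PlateauFit-method
#' @export
setMethod("riseSlope", "PlateauFit", function(x) x@beta1)
#' @rdname psiEstimate-PlateauFit-method
#' @export
setMethod("rSquared", "PlateauFit", function(x) x@r2)
#' @rdname psiEstimate-PlateauFit-method
#' @export
setMethod("isConverged", "PlateauFit", function(x) x@converged)
#' @rdname psiEstimate-PlateauFit-method
#' @export
setMethod("sseProfile", "PlateauFit", function(x) x@profile)

#' Accessors for FootprintRaster
#' @param x a [FootprintRaster-class] object.
#' @aliases rasterValues cellSize cellCenters
#' @export
setMethod("rasterValues", "FootprintRaster", function(x) x@values)
#' @rdname rasterValues-FootprintRaster-method
#' @export
setMethod("cellSize", "FootprintRaster", function(x) x@cellSize)
#' @rdname rasterValues-FootprintRaster-method
#' @export
setMethod("cellCenters", "FootprintRaster",
          function(x) list(x = x@xCenters, y = x@yCenters))

setMethod("show", "ProfileImage", function(object) {
  d <- dim(object@pixels)
  cat("ProfileImage '", object@imageId, "': ", d[1], " x ", d[2],
      " px RGB, ", format(object@mmPerPx), " mm/px (",
      format(d[2] * object@mmPerPx, digits = 4), " x ",
      format(d[1] * object@mmPerPx, digits = 4), " mm)\n", sep = "")
  if (length(object@position))
    cat("  position: ", paste(format(object@position, digits = 8),
                              collapse = ", "), "\n", sep = "")
})

setMethod("show", "PlateauFit", function(object) {
  cat("PlateauFit (rise-then-plateau segmented regression)\n")
  if (!object@converged) {
    cat("  NOT CONVERGED: breakpoint unidentifiable\n")
    return(invisible(NULL))
  }
  ci <- if (all(is.finite(object@psiCI)))
    sprintf(" [%.1f, %.1f]", object@psiCI[1], object@psiCI[2]) else ""
  cat(sprintf("  breakpoint psi: %.2f m%s\n", object@psi, ci))
  cat(sprintf("  plateau: %.2f grey, rise slope: %.4f grey/m\n",
              object@plateauLevel, object@beta1))
  cat(sprintf("  R2 = %.3f, SSE = %.4g, n = %d\n",
              object@r2, object@sse, object@n))
})

setMethod("show", "PlateauTruth", function(object) {
  cat(sprintf(
    "PlateauTruth: plateau %.1f grey, slope %.4f grey/m, psi %.1f m,\n",
    object@backgroundGrey, object@interiorSlope, object@breakpointM))
  cat(sprintf("  noise SD %.2f, n = %d over [%.0f, %.0f] m\n",
              object@noiseSd, object@nPoints,
              object@xRangeM[1], object@xRangeM[2]))
})

setMethod("show", "FootprintRaster", function(object) {
  cat(sprintf(
    "FootprintRaster: %d x %d cells of %.1f m (%s interpolation), %d no-data\n",
    length(object@xCenters), length(object@yCenters), object@cellSize,
    object@method, sum(is.na(object@values))))
})

setMethod("show", "AVSCalibration", function(object) {
  cat(sprintf("AVSCalibration: AVS = %.4g*grey^2 + %.4g*grey + %.4g umol/g\n",
              object@a, object@b, object@c))
  cat(sprintf("  calibrated grey range [%g, %g], individual CI +/- %g umol/g\n",
              object@validGreyRange[1], object@validGreyRange[2],
              object@ciHalfwidth))
})
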