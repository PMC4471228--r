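# S4 classes for the core data objects. Validity methods enforce the
# invariants the downstream operations rely on (channel ranges, positive
# scales, simple polygons, finite coefficients).

#' ProfileImage: an RGB sediment profile image with physical scale
#'
#' Pixels are stored as an integer-valued rows x cols x 3 array on the
#' 0--255 scale, row 1 at the top of the image (water above sediment).
#' `mmPerPx` converts pixel offsets to physical lengths; the field default
#' throughout the package is 0.08 mm per pixel (300 dpi class imagery).
#'
#' @slot pixels numeric array, rows x cols x 3, values in \[0, 255\].
#' @slot mmPerPx positive length scale, mm per pixel.
#' @slot imageId character identifier.
#' @slot position numeric(2) `(lon, lat)`, or empty when unknown.
#' @slot timestamp character timestamp, or empty.
#' @exportClass ProfileImage
setClass("ProfileImage",
  representation(
    pixels = "array",
    mmPerPx = "numeric",
    imageId = "character",
    position = "numeric",
    timestamp = "character"
  ),
  prototype(position = numeric(0), timestamp = character(0))
)

setValidity("ProfileImage", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3] != 3L)
    return("pixels must be a rows x cols x 3 array")
  if (anyNA(p) || min(p) < 0 || max(p) > 255)
    return("pixel values must lie in [0, 255]")
  if (length(object@mmPerPx) != 1L || !is.finite(object@mmPerPx) ||
      object@mmPerPx <= 0)
    return("mmPerPx must be a single positive number")
  if (length(object@position) && length(object@position) != 2L)
    return("position must be numeric(2) (lon, lat) or empty")
  TRUE
})

#' RegionOfInterest: pixel-space analysis region
#'
#' A closed, simple polygon (or axis-aligned rectangle, stored as its
#' polygon) over which mean intensity is computed. Vertices are
#' `(col, row)` pixel coordinates; pixel centers sit at integer
#' coordinates, so band ROIs use half-integer edges to make the
#' pixel-center containment test unambiguous.
#'
#' @slot mode `"rectangle"` or `"polygon"`.
#' @slot vertices numeric matrix, n x 2, columns `col`, `row`.
#' @exportClass RegionOfInterest
setClass("RegionOfInterest",
  representation(mode = "character", vertices = "matrix"))

setValidity("RegionOfInterest", function(object) {
  if (!object@mode %in% c("rectangle", "polygon"))
    return("mode must be 'rectangle' or 'polygon'")
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L || nrow(v) < 3L)
    return("vertices must be a numeric n x 2 matrix with n >= 3")
  if (anyNA(v)) return("vertices must be finite")
  a <- .polygonArea(v[, 1], v[, 2])
  if (abs(a) <= 0) return("polygon area must be > 0")
  TRUE
})

#' PlateauTruth: generating model for a transect grey-value series
#'
#' Ground truth for the linear-rise-to-plateau model
#' `grey(x) = background + slope * min(x - psi, 0) + N(0, sd^2)`,
#' where `x` is the signed distance from the farm boundary in metres
#' (negative inside the farm) and `psi` the breakpoint. If
#' `interiorSlope` is `NA` the constructor derives it so that the mean
#' grey of the points inside the farm (`x < 0`) equals `interiorMean`.
#'
#' @slot backgroundGrey plateau level, grey value in \[0, 255\].
#' @slot interiorSlope rise slope, grey per metre (> 0).
#' @slot breakpointM breakpoint, metres from the farm boundary.
#' @slot noiseSd Gaussian noise SD, grey values.
#' @slot nPoints number of sampling points (>= 4).
#' @slot xRangeM numeric(2), sampled distance range in metres.
#' @exportClass PlateauTruth
setClass("PlateauTruth",
  representation(
    backgroundGrey = "numeric",
    interiorSlope = "numeric",
    breakpointM = "numeric",
    noiseSd = "numeric",
    nPoints = "integer",
    xRangeM = "numeric"
  ))

setValidity("PlateauTruth", function(object) {
  if (object@backgroundGrey < 0 || object@backgroundGrey > 255)
    return("backgroundGrey must be in [0, 255]")
  if (!is.finite(object@interiorSlope) || object@interiorSlope <= 0)
    return("interiorSlope must be a positive finite number")
  r <- object@xRangeM
  if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2])
    return("xRangeM must be (min, max) with min < max")
  if (object@breakpointM < r[1] || object@breakpointM > r[2])
    return("breakpointM must lie within xRangeM")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@nPoints < 4L) return("nPoints must be >= 4")
  TRUE
})

#' ImageScenario: generating model for a synthetic profile image
#'
#' @slot targetGrey intended sediment-region mean grey in \[0, 255\].
#' @slot surfaceRowProfile per-analysis-column row of the first sediment
#'   pixel (recycled across columns).
#' @slot stripReference 9 x 3 matrix of reference swatch RGB values.
#' @slot colourDistortion 3 x 2 matrix, per-channel `(gain, offset)`
#'   applied to the rendered image (identity = gain 1, offset 0).
#' @slot textureSd Gaussian pixel noise SD in the sediment region.
#' @slot imageSize integer(2) `(rows, cols)`.
#' @slot mmPerPx length scale, mm per pixel.
#' @slot seed integer RNG seed.
#' @exportClass ImageScenario
setClass("ImageScenario",
  representation(
    targetGrey = "numeric",
    surfaceRowProfile = "numeric",
    stripReference = "matrix",
    colourDistortion = "matrix",
    textureSd = "numeric",
    imageSize = "integer",
    mmPerPx = "numeric",
    seed = "integer"
  ))

setValidity("ImageScenario", function(object) {
  sz <- object@imageSize
  if (length(sz) != 2L || any(sz < 8L))
    return("imageSize must be (rows, cols), both >= 8")
  if (object@mmPerPx <= 0) return("mmPerPx must be > 0")
  if (object@targetGrey < 0 || object@targetGrey > 255)
    return("targetGrey must be in [0, 255]")
  d <- object@colourDistortion
  if (!all(dim(d) == c(3L, 2L))) return("colourDistortion must be 3 x 2")
  if (any(d[, 1] == 0)) return("distortion gains must be non-zero")
  srf <- object@surfaceRowProfile
  if (any(srf < 2) || any(srf > sz[1]))
    return("surfaceRowProfile rows must lie within the image")
  if (!all(dim(object@stripReference) == c(9L, 3L)))
    return("stripReference must be a 9 x 3 RGB matrix")
  if (object@textureSd < 0) return("textureSd must be >= 0")
  TRUE
})

#' AVSCalibration: quadratic grey-to-AVS conversion
#'
#' `AVS = a * grey^2 + b * grey + c`, AVS in umol per g sediment.
#' Defaults are the published Awakiriapa Bay coefficients; the numeric
#' validity range of the grey values behind that calibration is not
#' published, so `validGreyRange` is a configurable package choice.
#'
#' @slot a,b,c quadratic coefficients.
#' @slot validGreyRange numeric(2), grey range over which the calibration
#'   is considered interpolation rather than extrapolation.
#' @slot ciHalfwidth mean 95% individual CI of the calibration, umol/g.
#' @exportClass AVSCalibration
setClass("AVSCalibration",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 validGreyRange = "numeric", ciHalfwidth = "numeric"))

setValidity("AVSCalibration", function(object) {
  if (!all(is.finite(c(object@a, object@b, object@c))))
    return("coefficients must be finite")
  r <- object@validGreyRange
  if (length(r) != 2L || r[1] >= r[2])
    return("validGreyRange must be (lo, hi) with lo < hi")
  TRUE
})

#' PlateauFit: fitted rise-then-plateau segmented regression
#'
#' Model `grey(x) = plateau + beta1 * min(x - psi, 0)`; equivalently
#' intercept form `beta0 + beta1 * x` left of the breakpoint with
#' `beta0 = plateau - beta1 * psi`. The slope of the far-field segment is
#' constrained to zero (background sediment has no long-distance colour
#' trend), so `plateauLevel == beta0 + beta1 * psi` holds by construction.
#'
#' @slot psi breakpoint estimate, metres from the farm boundary.
#' @slot psiCI numeric(2) confidence bounds (NA until [breakpointCI()]).
#' @slot ciLevel level of `psiCI`.
#' @slot beta0 intercept of the rising segment (grey).
#' @slot beta1 rise slope (grey per metre).
#' @slot plateauLevel background plateau (grey).
#' @slot r2 coefficient of determination.
#' @slot sse residual sum of squares.
#' @slot n number of observations.
#' @slot converged FALSE when the breakpoint is unidentifiable.
#' @slot psi0Used starting value recorded for the profile scan.
#' @slot profile data.frame of the SSE profile (`psi`, `sse`) diagnostics.
#' @slot xRange numeric(2) observed x range.
#' @slot mirrored TRUE for the plateau-then-rise orientation.
#' @exportClass PlateauFit
setClass("PlateauFit",
  representation(
    psi = "numeric", psiCI = "numeric", ciLevel = "numeric",
    beta0 = "numeric", beta1 = "numeric", plateauLevel = "numeric",
    r2 = "numeric", sse = "numeric", n = "integer",
    converged = "logical", psi0Used = "numeric",
    profile = "data.frame", xRange = "numeric", mirrored = "logical"
  ),
  prototype(psiCI = c(NA_real_, NA_real_), ciLevel = NA_real_,
            mirrored = FALSE))

setValidity("PlateauFit", function(object) {
  if (isTRUE(object@converged)) {
    if (object@psi < object@xRange[1] || object@psi > object@xRange[2])
      return("psi must lie within the observed x range")
    if (is.finite(object@r2) && (object@r2 < -1e-9 || object@r2 > 1 + 1e-9))
      return("r2 must lie in [0, 1]")
    pl <- object@beta0 + object@beta1 * object@psi
    if (abs(pl - object@plateauLevel) > 1e-6 * (1 + abs(pl)))
      return("plateauLevel must equal beta0 + beta1 * psi")
  }
  TRUE
})

#' FarmBoundary: farm polygon with a designated northern edge
#'
#' @slot vertices n x 2 matrix of polygon vertices (`x`, `y` local metres
#'   or `lon`, `lat`), not closed (first vertex is not repeated).
#' @slot northern m x 2 matrix, polyline of the northern boundary used for
#'   distance calculations.
#' @slot crs `"local"` (metres) or `"lonlat"` (degrees).
#' @exportClass FarmBoundary
setClass("FarmBoundary",
  representation(vertices = "matrix", northern = "matrix",
                 crs = "character"))

setValidity("FarmBoundary", function(object) {
  if (nrow(object@vertices) < 3L) return("farm polygon needs >= 3 vertices")
  if (nrow(object@northern) < 2L) return("northern edge needs >= 2 vertices")
  d <- diff(object@northern)
  if (any(rowSums(d^2) == 0)) return("repeated consecutive vertices")
  if (!object@crs %in% c("local", "lonlat"))
    return("crs must be 'local' or 'lonlat'")
  TRUE
})

#' FootprintRaster: interpolated grey-value grid in local metres
#'
#' `values[i, j]` is the interpolated grey at `(xCenters[i], yCenters[j])`;
#' `NA` marks cells beyond the extrapolation limit.
#'
#' @slot xCenters,yCenters ascending cell-center coordinates, metres.
#' @slot values numeric matrix, `length(xCenters)` x `length(yCenters)`.
#' @slot cellSize cell edge, metres.
#' @slot method interpolation method used.
#' @exportClass FootprintRaster
setClass("FootprintRaster",
  representation(xCenters = "numeric", yCenters = "numeric",
                 values = "matrix", cellSize = "numeric",
                 method = "character"))

setValidity("FootprintRaster", function(object) {
  if (object@cellSize <= 0) return("cellSize must be > 0")
  if (!all(dim(object@values) ==
           c(length(object@xCenters), length(object@yCenters))))
    return("values must be length(xCenters) x length(yCenters)")
  v <- object@values[!is.na(object@values)]
  if (length(v) && (min(v) < -1e-9 || max(v) > 255 + 1e-9))
    return("raster values must be in [0, 255] or NA")
  TRUE
})
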