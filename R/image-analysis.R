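# Colour calibration, HSI intensity, surface detection, region-of-
# interest construction and mean grey measurement.

#' Calibrate image colours against the embedded reference strip
#'
#' Estimates a per-channel affine correction by least squares from the
#' measured swatch means versus the reference values, then inverts it on
#' every pixel so that colour reproduction is identical across images:
#' `corrected = (value - offset) / gain`, clipped to \[0, 255\].
#' Only swatches whose reference value lies strictly inside (0, 255) on
#' the channel enter the regression (the extreme swatches are the ones
#' 8-bit clipping censors under gain/offset distortions, which would
#' bias the fit and break idempotency); measured means within half a
#' grey of 0 or 255 are additionally dropped as saturated. At least
#' three usable swatches per channel are required.
#'
#' @param img a [ProfileImage-class].
#' @param stripReference 9 x 3 reference swatch RGB matrix.
#' @param stripLoc strip location as returned by [stripLocation()]
#'   (list with `cols` and `swatchRows`); default assumes the standard
#'   right-edge layout for the image's size.
#' @return The corrected [ProfileImage-class]; the estimated per-channel
#'   `(gain, offset)` matrix is attached as attribute `"calibration"`
#'   and retrievable with [calibrationCoefficients()].
#' @export
calibrateColours <- function(img, stripReference = spiStripReference(),
                             stripLoc = NULL) {
  stopifnot(is(img, "ProfileImage"))
  px <- imagePixels(img)
  if (is.null(stripLoc)) stripLoc <- stripLocation(dim(px)[1], dim(px)[2])
  measured <- .measureSwatches(px, stripLoc)
  coefs <- matrix(NA_real_, 3, 2,
                  dimnames = list(c("R", "G", "B"), c("gain", "offset")))
  for (ch in 1:3) {
    ref <- stripReference[, ch]
    obs <- measured[, ch]
    usable <- ref > 0 & ref < 255 & obs > 0.5 & obs < 254.5
    if (sum(usable) < 3)
      stop("calibration failure: fewer than 3 unsaturated swatches on ",
           c("R", "G", "B")[ch], " channel")
    if (sd(ref[usable]) == 0)
      stop("calibration failure: degenerate (constant) reference swatches")
    fit <- lm(obs[usable] ~ ref[usable])
    gain <- unname(coef(fit)[2]); off <- unname(coef(fit)[1])
    if (!is.finite(gain) || abs(gain) < 1e-3)
      stop("calibration failure: near-zero gain on ",
           c("R", "G", "B")[ch], " channel (constant measured swatches)")
    coefs[ch, ] <- c(gain, off)
    px[, , ch] <- .clip255((px[, , ch] - off) / gain)
  }
  out <- new("ProfileImage", pixels = px, mmPerPx = img@mmPerPx,
             imageId = img@imageId, position = img@position,
             timestamp = img@timestamp)
  attr(out, "calibration") <- coefs
  out
}

#' @rdname calibrateColours
#' @export
calibrationCoefficients <- function(img) attr(img, "calibration")

# Mean RGB per swatch over the strip blocks, 1 px inset from block edges.
.measureSwatches <- function(px, stripLoc) {
  cols <- (stripLoc$cols[1] + 1L):(stripLoc$cols[2] - 1L)
  out <- matrix(NA_real_, 9, 3)
  for (s in 1:9) {
    rws <- (stripLoc$swatchRows[s, 1] + 1L):(stripLoc$swatchRows[s, 2] - 1L)
    for (ch in 1:3) out[s, ch] <- mean(px[rws, cols, ch])
  }
  out
}

#' Convert an RGB image to HSI intensity
#'
#' The intensity channel of the classical HSI colour space:
#' `I = (R + G + B) / 3` on the 0--255 scale, real-valued (not
#' re-quantised). The weights are configurable for other intensity
#' definitions.
#'
#' @param img a [ProfileImage-class] or rows x cols x 3 array.
#' @param weights channel weights summing to 1.
#' @return Numeric matrix of intensities (rows x cols).
#' @examples
#' rgbToIntensity(array(c(255, 0, 0), c(1, 1, 3)))  # 85
#' @export
rgbToIntensity <- function(img, weights = c(1, 1, 1) / 3) {
  px <- if (is(img, "ProfileImage")) imagePixels(img) else img
  stopifnot(length(dim(px)) == 3L, dim(px)[3] == 3L)
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  matrix(px[, , 1] * weights[1] + px[, , 2] * weights[2] +
           px[, , 3] * weights[3], dim(px)[1], dim(px)[2])
}

#' Detect the sediment-water interface
#'
#' Per column, the interface is placed at the maximum downward intensity
#' drop after median smoothing (water is bright, sediment dark). Columns
#' where no drop exceeds `minContrast` are interpolated from their
#' neighbours; if more than half the columns fail, detection errors out
#' and a manual contour should be supplied. A user-supplied `contour`
#' always overrides detection.
#'
#' @param intensity intensity matrix from [rgbToIntensity()].
#' @param columns columns to analyse (default: all). Crop the
#'   calibration strip before detection.
#' @param smoothWidth per-column median filter width (odd, px).
#' @param minContrast minimum intensity drop (grey values).
#' @param contour optional manual contour (row per column) returned
#'   as-is.
#' @return Numeric vector: row index of the first sediment pixel per
#'   column, with the analysed columns in attribute `"columns"`.
#' @export
detectSurface <- function(intensity, columns = NULL, smoothWidth = 9,
                          minContrast = 20, contour = NULL) {
  if (!is.null(contour)) return(contour)
  if (is.null(columns)) columns <- seq_len(ncol(intensity))
  rows <- nrow(intensity)
  srf <- rep(NA_real_, length(columns))
  for (k in seq_along(columns)) {
    v <- intensity[, columns[k]]
    if (rows > smoothWidth) v <- runmed(v, smoothWidth)
    drop <- -diff(v)
    if (length(drop) && max(drop) >= minContrast)
      srf[k] <- which.max(drop) + 1L
  }
  bad <- is.na(srf)
  if (mean(bad) > 0.5)
    stop("surface detection failure: no intensity drop >= ", minContrast,
         " grey values in most columns; supply a manual contour")
  if (any(bad))
    srf[bad] <- round(stats::approx(which(!bad), srf[!bad],
                                    xout = which(bad), rule = 2)$y)
  attr(srf, "columns") <- columns
  srf
}

#' Build the analysis region of interest below the sediment surface
#'
#' Polygon mode follows the surface contour from `topOffsetMm` below the
#' surface down a further `extentMm` (the default band runs from 10 mm
#' to 50 mm below the surface). Rectangle mode anchors an axis-aligned
#' band of the same vertical extent at the deepest surface point. Pixel
#' conversion is `round(offset / mmPerPx)`.
#'
#' When the band would run past the image bottom the default is an error
#' naming the shortfall; `clip = TRUE` instead truncates the band at the
#' image bottom with a warning (the field situation in which a
#' deepest-anchored rectangle captures fewer pixels than the
#' contour-following polygon).
#'
#' @param surface surface contour from [detectSurface()].
#' @param mode `"polygon"` (default; contour-following, the less
#'   ambiguous choice) or `"rectangle"`.
#' @param topOffsetMm gap between surface and band top, mm.
#' @param extentMm band depth, mm.
#' @param mmPerPx physical scale, mm per pixel.
#' @param imageRows number of pixel rows in the image.
#' @param clip truncate at the image bottom instead of erroring.
#' @return A [RegionOfInterest-class].
#' @examples
#' roi <- makeRoi(rep(100, 50), "rectangle", mmPerPx = 0.08,
#'                imageRows = 800)
#' @export
makeRoi <- function(surface, mode = c("polygon", "rectangle"),
                    topOffsetMm = 10, extentMm = 40, mmPerPx = 0.08,
                    imageRows, clip = FALSE) {
  mode <- match.arg(mode)
  columns <- attr(surface, "columns")
  if (is.null(columns)) columns <- seq_along(surface)
  offPx <- round(topOffsetMm / mmPerPx)
  extPx <- round(extentMm / mmPerPx)
  if (mode == "rectangle") {
    top <- rep(max(surface) + offPx, length(columns))
  } else {
    top <- surface + offPx
  }
  bottom <- top + extPx - 1
  over <- max(bottom) - imageRows
  if (over > 0) {
    if (!clip)
      stop(sprintf(
        "ROI band exceeds image bottom by %d px (%.1f mm); reduce ",
        over, over * mmPerPx), "offset/extent or use clip = TRUE")
    warning(sprintf("ROI band clipped at image bottom (%.1f mm short)",
                    over * mmPerPx))
    bottom <- pmin(bottom, imageRows)
    keep <- top <= imageRows
    if (!any(keep)) stop("ROI band empty after clipping")
    columns <- columns[keep]; top <- top[keep]; bottom <- bottom[keep]
  }
  # step polygon with half-integer edges so pixel-center containment is
  # exact: pixel (row, col) is inside iff top <= row <= bottom
  n <- length(columns)
  vx <- c(rbind(columns - 0.5, columns + 0.5),
          rev(c(rbind(columns - 0.5, columns + 0.5))))
  vy <- c(rbind(top - 0.5, top - 0.5),
          rev(c(rbind(bottom + 0.5, bottom + 0.5))))
  new("RegionOfInterest", mode = mode, vertices = cbind(col = vx, row = vy))
}

#' Mean intensity over a region of interest
#'
#' Arithmetic mean of the intensity at pixels whose centers (integer
#' row/col coordinates) fall inside the ROI polygon under the even-odd
#' rule.
#'
#' @param intensity intensity matrix from [rgbToIntensity()], or a
#'   [ProfileImage-class] (converted with default weights).
#' @param roi a [RegionOfInterest-class].
#' @param imageId identifier carried into the result.
#' @return One-row `data.frame`: `image_id`, `mean_grey`, `pixel_count`,
#'   `roi_mode`.
#' @export
meanIntensity <- function(intensity, roi, imageId = "") {
  if (is(intensity, "ProfileImage")) {
    if (imageId == "") imageId <- intensity@imageId
    intensity <- rgbToIntensity(intensity)
  }
  stopifnot(is(roi, "RegionOfInterest"))
  v <- roiVertices(roi)
  cmin <- max(1L, ceiling(min(v[, 1]))); cmax <- min(ncol(intensity), floor(max(v[, 1])))
  rmin <- max(1L, ceiling(min(v[, 2]))); rmax <- min(nrow(intensity), floor(max(v[, 2])))
  if (cmin > cmax || rmin > rmax) stop("empty ROI: no pixel centers inside")
  cc <- rep(cmin:cmax, each = rmax - rmin + 1L)
  rr <- rep(rmin:rmax, times = cmax - cmin + 1L)
  inside <- .pointInPolygon(cc, rr, v[, 1], v[, 2])
  if (!any(inside)) stop("empty ROI: no pixel centers inside")
  vals <- intensity[cbind(rr[inside], cc[inside])]
  data.frame(image_id = imageId, mean_grey = mean(vals),
             pixel_count = sum(inside), roi_mode = roiMode(roi),
             stringsAsFactors = FALSE)
}
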