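# Synthetic sediment profile images: bright low-texture water above a
# (possibly sloped) sediment surface, achromatic sediment with a target
# mean grey, and a right-edge calibration strip, all optionally passed
# through a per-channel affine colour distortion. A sidecar records the
# exact ground truth so the image pipeline can be checked against it.

#' Reference swatch values of the calibration strip
#'
#' Nine swatches rendered top to bottom on the right edge of every
#' synthetic image: six grey swatches spanning 0--255 (0, 51, 102, 153,
#' 204, 255) followed by pure red, green and blue primaries. These are a
#' package constant; colour calibration regresses measured swatch means
#' against them.
#'
#' @return A 9 x 3 numeric matrix of RGB values.
#' @export
spiStripReference <- function() {
  g <- c(0, 51, 102, 153, 204, 255)
  ref <- rbind(cbind(g, g, g),
               c(255, 0, 0), c(0, 255, 0), c(0, 0, 255))
  dimnames(ref) <- list(
    c(paste0("grey", g), "red", "green", "blue"), c("R", "G", "B"))
  ref
}

# Standard strip layout: a right-edge column band, 9 equal-height swatch
# blocks. Returns the band columns and per-swatch row ranges.
.stripLayout <- function(rows, cols) {
  sw <- max(10L, round(0.1 * cols))
  bounds <- floor(seq(0, rows, length.out = 10L))
  list(cols = c(cols - sw + 1L, cols),
       swatchRows = cbind(bounds[-10] + 1L, bounds[-1]))
}

#' Locate the calibration strip in an image of given size
#'
#' @param rows,cols image dimensions in pixels.
#' @return list with `cols` (first and last strip column) and
#'   `swatchRows` (9 x 2 matrix of first/last row per swatch).
#' @export
stripLocation <- function(rows, cols) .stripLayout(rows, cols)

#' Construct a synthetic profile-image scenario
#'
#' @param targetGrey intended sediment-region mean grey (0--255).
#' @param surfaceRowProfile per-column row of the first sediment pixel
#'   over the analysis band (left of the strip); a single value gives a
#'   flat surface. Default: flat at one third of the image height, so
#'   sediment fills the lower two thirds.
#' @param stripReference 9 x 3 swatch RGB matrix, see
#'   [spiStripReference()].
#' @param colourDistortion 3 x 2 matrix of per-channel `(gain, offset)`
#'   applied to the whole rendered image; identity by default.
#' @param textureSd Gaussian pixel noise SD in the sediment region.
#' @param imageSize integer(2) `(rows, cols)`.
#' @param mmPerPx physical scale, mm per pixel.
#' @param seed integer RNG seed.
#' @return An [ImageScenario-class] object.
#' @export
imageScenario <- function(targetGrey = 75, surfaceRowProfile = NULL,
                          stripReference = spiStripReference(),
                          colourDistortion = cbind(gain = c(1, 1, 1),
                                                   offset = c(0, 0, 0)),
                          textureSd = 4, imageSize = c(240, 200),
                          mmPerPx = 0.08, seed = 1L) {
  imageSize <- as.integer(imageSize)
  if (is.null(surfaceRowProfile))
    surfaceRowProfile <- round(imageSize[1] / 3)
  nac <- imageSize[2] - .stripLayout(imageSize[1], imageSize[2])$cols[1] + 1L
  nac <- imageSize[2] - nac
  surfaceRowProfile <- rep_len(as.numeric(surfaceRowProfile), nac)
  new("ImageScenario", targetGrey = targetGrey,
      surfaceRowProfile = surfaceRowProfile,
      stripReference = as.matrix(stripReference),
      colourDistortion = as.matrix(colourDistortion),
      textureSd = textureSd, imageSize = imageSize,
      mmPerPx = mmPerPx, seed = as.integer(seed))
}

#' Generate a synthetic sediment profile image with ground truth
#'
#' Renders water (bright, low texture) above the surface row profile,
#' achromatic sediment whose distortion-free mean intensity equals the
#' scenario's target grey (up to texture noise and 8-bit rounding; the
#' exact realized mean is recorded), and the calibration strip, then
#' applies the per-channel affine colour distortion with clipping to
#' \[0, 255\].
#'
#' @param scenario an [ImageScenario-class] object.
#' @param imageId identifier stored in the image and sidecar.
#' @return list with elements `image` (a [ProfileImage-class]) and
#'   `truth`, the ground-truth sidecar: `targetGrey`,
#'   `realizedSedimentMean` (after rounding/clipping, before
#'   distortion), `surfaceRows`, `stripCols`, `swatchRows`,
#'   `distortion`, `mmPerPx`, `seed`.
#' @examples
#' g <- generateProfileImage(imageScenario(textureSd = 0))
#' g$truth$realizedSedimentMean
#' @export
generateProfileImage <- function(scenario, imageId = "synthetic") {
  stopifnot(is(scenario, "ImageScenario"))
  validObject(scenario)
  rows <- scenario@imageSize[1]; cols <- scenario@imageSize[2]
  lay <- .stripLayout(rows, cols)
  acols <- seq_len(lay$cols[1] - 1L)
  srf <- round(scenario@surfaceRowProfile)
  if (any(srf > rows))
    stop("surface profile exceeds image rows")
  .withSeed(scenario@seed, {
    px <- array(0, dim = c(rows, cols, 3))
    # water: bluish-bright, very low texture
    waterBase <- c(190, 205, 215)
    for (ch in 1:3)
      px[, acols, ch] <- waterBase[ch] + rnorm(rows * length(acols), 0, 1)
    # sediment: achromatic target grey + texture, rounded to 8 bit
    sed <- matrix(FALSE, rows, length(acols))
    for (j in seq_along(acols)) sed[srf[j]:rows, j] <- TRUE
    g <- scenario@targetGrey + rnorm(sum(sed), 0, scenario@textureSd)
    g <- round(.clip255(g))
    for (ch in 1:3) {
      plane <- px[, acols, ch]
      plane[sed] <- g
      px[, acols, ch] <- plane
    }
    realized <- mean(g)
    # calibration strip
    stripCols <- lay$cols[1]:lay$cols[2]
    for (s in 1:9) {
      rws <- lay$swatchRows[s, 1]:lay$swatchRows[s, 2]
      for (ch in 1:3) px[rws, stripCols, ch] <- scenario@stripReference[s, ch]
    }
    px <- round(.clip255(px))
    # per-channel affine distortion of the whole image, clipped to 8 bit
    dist <- scenario@colourDistortion
    for (ch in 1:3)
      px[, , ch] <- round(.clip255(dist[ch, 1] * px[, , ch] + dist[ch, 2]))
    img <- new("ProfileImage", pixels = px, mmPerPx = scenario@mmPerPx,
               imageId = imageId)
    truth <- list(
      imageId = imageId,
      targetGrey = scenario@targetGrey,
      realizedSedimentMean = realized,
      surfaceRows = srf,
      analysisCols = acols,
      stripCols = lay$cols,
      swatchRows = lay$swatchRows,
      distortion = dist,
      mmPerPx = scenario@mmPerPx,
      seed = scenario@seed)
    list(image = img, truth = truth)
  })
}

#' Write a profile image as lossless PNG with a JSON sidecar
#'
#' PNG is used for synthesis because it is lossless; JPEG would corrupt
#' the controlled pixel statistics.
#'
#' @param image a [ProfileImage-class].
#' @param path output path ending in `.png`.
#' @param sidecar optional list written as `<path>.json` (with the
#'   `.png` suffix replaced); image id, position, timestamp and any
#'   ground truth fields.
#' @return `path`, invisibly.
#' @export
writeProfileImage <- function(image, path, sidecar = NULL) {
  stopifnot(is(image, "ProfileImage"))
  png::writePNG(imagePixels(image) / 255, path)
  meta <- c(list(image_id = imageId(image),
                 mm_per_px = mmPerPx(image)), sidecar)
  if (length(image@position))
    meta[c("lon", "lat")] <- as.list(image@position)
  if (length(image@timestamp)) meta$timestamp <- image@timestamp
  jsonlite::write_json(meta, sub("\\.png$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
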