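# Image input. PNG and TIFF via the png/tiff packages; JPEG via the
# jpeg package when available. 16-bit TIFFs are rescaled to the 0--255
# working scale.

#' Read a sediment profile image
#'
#' Decodes a PNG, TIFF or JPEG file into a [ProfileImage-class]. The
#' image must have three colour channels (an alpha channel is dropped);
#' single-channel greyscale files are rejected because the calibration
#' and HSI conversion need RGB. 16-bit TIFF values are rescaled to
#' 0--255 (`round(value / 257)`) with a message. If `<path>.json` (the
#' `.png`/`.tif` suffix replaced by `.json`) exists it is read as a
#' sidecar supplying `image_id`, `lon`, `lat`, `timestamp` and
#' `mm_per_px`.
#'
#' @param path image file path.
#' @param mmPerPx physical scale used when the sidecar does not supply
#'   one; the package default is 0.08 mm per pixel.
#' @param imageId identifier; defaults to the sidecar value or the file
#'   name.
#' @return A [ProfileImage-class] object.
#' @export
readProfileImage <- function(path, mmPerPx = 0.08, imageId = NULL) {
  if (!file.exists(path)) stop("cannot read image: no such file ", path)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path) * 255,
    tif = , tiff = {
      v <- tiff::readTIFF(path, info = TRUE)
      bits <- attr(v, "bits.per.sample")
      # normalised * 255 == raw 16-bit value / 257 (65535 / 255 = 257)
      if (!is.null(bits) && bits > 8)
        message("16-bit TIFF '", basename(path), "' rescaled to 0-255")
      v * 255
    },
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path) * 255
    },
    stop("cannot decode '", path, "': unsupported extension .", ext))
  if (length(dim(a)) < 3L)
    stop("image '", path, "' has 1 channel; 3-channel RGB required")
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] != 3L)
    stop("image '", path, "' has ", dim(a)[3],
         " channels; 3-channel RGB required")
  a <- round(a)
  scPath <- sub("\\.[A-Za-z]+$", ".json", path)
  pos <- numeric(0); ts <- character(0)
  if (file.exists(scPath)) {
    sc <- jsonlite::read_json(scPath, simplifyVector = TRUE)
    if (!is.null(sc$mm_per_px)) mmPerPx <- sc$mm_per_px
    if (is.null(imageId) && !is.null(sc$image_id)) imageId <- sc$image_id
    if (!is.null(sc$lon) && !is.null(sc$lat))
      pos <- c(sc$lon, sc$lat)
    if (!is.null(sc$timestamp)) ts <- sc$timestamp
  }
  if (is.null(imageId)) imageId <- tools::file_path_sans_ext(basename(path))
  new("ProfileImage", pixels = a, mmPerPx = mmPerPx, imageId = imageId,
      position = pos, timestamp = ts)
}
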