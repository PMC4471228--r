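# Spatial footprint mapping: signed distances to the farm's northern
# boundary, interpolation of grey values onto a metric raster, and
# iso-contour extraction of the footprint edge.

#' Construct a farm boundary
#'
#' @param vertices n x 2 matrix or data.frame of polygon vertices,
#'   `(x, y)` in local metres or `(lon, lat)` in degrees. A repeated
#'   closing vertex is dropped.
#' @param northern optional m x 2 matrix giving the northern boundary
#'   polyline used for distance calculations. By default the chain of
#'   polygon vertices at the maximum y (or latitude) is used; if no
#'   edge is level with the top, the edge whose midpoint is
#'   northernmost.
#' @param crs `"local"` (metres) or `"lonlat"`.
#' @return A [FarmBoundary-class] object.
#' @examples
#' fb <- farmBoundary(rbind(c(0, -400), c(600, -400), c(600, 0), c(0, 0)))
#' @export
farmBoundary <- function(vertices, northern = NULL,
                         crs = c("local", "lonlat")) {
  crs <- match.arg(crs)
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  n <- nrow(v)
  if (n > 1 && all(v[1, ] == v[n, ])) v <- v[-n, , drop = FALSE]
  if (is.null(northern)) {
    ymax <- max(v[, 2])
    tol <- 1e-9 * (diff(range(v[, 2])) + 1)
    top <- which(v[, 2] >= ymax - tol)
    if (length(top) >= 2) {
      northern <- v[sort(top), , drop = FALSE]
      northern <- northern[order(northern[, 1]), , drop = FALSE]
    } else {
      nn <- nrow(v)
      midY <- (v[, 2] + v[c(2:nn, 1), 2]) / 2
      e <- which.max(midY)
      northern <- v[c(e, e %% nn + 1), , drop = FALSE]
    }
  } else {
    northern <- as.matrix(northern)
    storage.mode(northern) <- "double"
  }
  new("FarmBoundary", vertices = v, northern = northern, crs = crs)
}

# Equirectangular projection (degrees -> local metres) about a center.
.projectLonLat <- function(lonlat, center) {
  R <- 6371000
  rad <- pi / 180
  cbind((lonlat[, 1] - center[1]) * cos(center[2] * rad) * R * rad,
        (lonlat[, 2] - center[2]) * R * rad)
}

#' Signed distance from points to the farm's northern boundary
#'
#' Euclidean distance from each point to the nearest segment of the
#' northern boundary polyline, negative for points inside the farm
#' polygon and positive outside. Lon/lat inputs are projected to local
#' metres with an equirectangular projection centered on the data
#' (adequate at survey extents up to about a kilometre); a warning is
#' issued for points farther than 10 km from the boundary, where that
#' projection degrades.
#'
#' @param points n x 2 matrix/data.frame of positions in the boundary's
#'   coordinate system.
#' @param boundary a [FarmBoundary-class].
#' @param center optional projection center `(lon, lat)`; default is
#'   the centroid of the points and the northern boundary. The result
#'   is insensitive to this choice within the survey extent.
#' @return Numeric vector of signed distances in metres.
#' @examples
#' fb <- demoFarmBoundary()
#' signedDistance(rbind(c(300, 56), c(300, -10)), fb)
#' @export
signedDistance <- function(points, boundary, center = NULL) {
  stopifnot(is(boundary, "FarmBoundary"))
  p <- as.matrix(points)
  storage.mode(p) <- "double"
  poly <- boundary@vertices
  north <- boundary@northern
  if (boundary@crs == "lonlat") {
    if (is.null(center))
      center <- colMeans(rbind(p, north))
    p <- .projectLonLat(p, center)
    poly <- .projectLonLat(poly, center)
    north <- .projectLonLat(north, center)
  }
  d <- rep(Inf, nrow(p))
  for (i in seq_len(nrow(north) - 1L)) {
    d <- pmin(d, .pointSegDist(p[, 1], p[, 2],
                               north[i, 1], north[i, 2],
                               north[i + 1, 1], north[i + 1, 2]))
  }
  if (any(d > 10000))
    warning("points more than 10 km from the boundary: ",
            "local projection may be inaccurate")
  inside <- .pointInPolygon(p[, 1], p[, 2], poly[, 1], poly[, 2])
  ifelse(inside, -d, d)
}

#' Interpolate grey values onto a footprint raster
#'
#' Two interpolators over a regular metric grid: `"localPolynomial"`
#' (default), a first-order polynomial fitted by weighted least squares
#' at each cell with Gaussian distance weights of the given bandwidth;
#' and `"idw"`, inverse-distance weighting with the given power, which
#' honours the data exactly at data-point locations. Cells whose nearest
#' data point is farther than `maxDist` are masked as no-data; values
#' are clamped to the grey scale \[0, 255\].
#'
#' @param points n x 2 matrix of local metric positions.
#' @param values grey values at the points.
#' @param gridSpec list with `xlim`, `ylim` (metres) and `cellSize`
#'   (default 5 m); defaults to the padded bounding box of the points.
#' @param method `"localPolynomial"` or `"idw"`.
#' @param params list: `bandwidth` (m, Gaussian kernel SD for the local
#'   polynomial, default 25), `power` (idw exponent, default 2),
#'   `maxDist` (extrapolation mask distance, default 100 m),
#'   `minNeighbors` (minimum points for a local fit, default 6).
#' @return A [FootprintRaster-class].
#' @export
interpolateGrey <- function(points, values, gridSpec = NULL,
                            method = c("localPolynomial", "idw"),
                            params = list()) {
  method <- match.arg(method)
  p <- as.matrix(points)
  storage.mode(p) <- "double"
  stopifnot(nrow(p) == length(values))
  prm <- utils::modifyList(
    list(bandwidth = 25, power = 2, maxDist = 100, minNeighbors = 6),
    params)
  if (prm$bandwidth <= 0) stop("bandwidth must be > 0")
  if (is.null(gridSpec)) gridSpec <- list()
  cs <- gridSpec$cellSize %||% 5
  xlim <- gridSpec$xlim %||% (range(p[, 1]) + c(-cs, cs))
  ylim <- gridSpec$ylim %||% (range(p[, 2]) + c(-cs, cs))
  xc <- seq(xlim[1] + cs / 2, xlim[2], by = cs)
  yc <- seq(ylim[1] + cs / 2, ylim[2], by = cs)
  if (method == "localPolynomial") {
    if (nrow(p) < 3) stop("local polynomial needs >= 3 points")
    if (qr(cbind(1, p))$rank < 3) {
      warning("all points collinear; falling back to idw")
      method <- "idw"
    }
  }
  z <- matrix(NA_real_, length(xc), length(yc))
  h <- prm$bandwidth
  for (j in seq_along(yc)) {
    for (i in seq_along(xc)) {
      dx <- p[, 1] - xc[i]; dy <- p[, 2] - yc[j]
      d2 <- dx * dx + dy * dy
      dmin <- sqrt(min(d2))
      if (dmin > prm$maxDist) next
      if (method == "idw") {
        if (dmin < 1e-9) {
          z[i, j] <- values[which.min(d2)]
        } else {
          w <- 1 / d2^(prm$power / 2)
          z[i, j] <- sum(w * values) / sum(w)
        }
      } else {
        w <- exp(-0.5 * d2 / h^2)
        use <- which(w > 1e-12)
        if (length(use) < prm$minNeighbors)
          use <- order(d2)[seq_len(min(prm$minNeighbors, nrow(p)))]
        X <- cbind(1, dx[use], dy[use])
        wt <- pmax(w[use], 1e-12)
        fit <- tryCatch(stats::lm.wfit(X, values[use], wt),
                        error = function(e) NULL)
        z[i, j] <- if (!is.null(fit) && fit$rank == 3L &&
                       is.finite(fit$coefficients[1]))
          fit$coefficients[1]
        else sum(wt * values[use]) / sum(wt)  # degenerate: weighted mean
      }
    }
  }
  z[!is.na(z)] <- .clip255(z[!is.na(z)])
  new("FootprintRaster", xCenters = xc, yCenters = yc, values = z,
      cellSize = cs, method = method)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the footprint iso-contour from a raster
#'
#' Marching-squares style iso-lines (via [grDevices::contourLines()]) at
#' the given grey threshold; vertices are in local metres.
#'
#' @param raster a [FootprintRaster-class].
#' @param threshold grey value of the contour, typically midway between
#'   the interior and plateau levels.
#' @return list of contour polylines (each an m x 2 matrix with columns
#'   `x`, `y`); empty, with a warning, when the threshold is outside
#'   the raster's value range.
#' @export
footprintContour <- function(raster, threshold) {
  stopifnot(is(raster, "FootprintRaster"))
  v <- raster@values
  rng <- range(v, na.rm = TRUE)
  if (threshold < rng[1] || threshold > rng[2]) {
    warning(sprintf(
      "threshold %.1f outside raster value range [%.1f, %.1f]",
      threshold, rng[1], rng[2]))
    return(list())
  }
  cl <- contourLines(raster@xCenters, raster@yCenters, v,
                     levels = threshold)
  lapply(cl, function(c1) cbind(x = c1$x, y = c1$y))
}

#' Write a raster as an Esri ASCII grid
#'
#' Plain-text grid format readable by standard GIS software; rows run
#' north to south.
#'
#' @param raster a [FootprintRaster-class].
#' @param path output path (conventionally `.asc`).
#' @param nodata no-data sentinel value.
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(raster, path, nodata = -9999) {
  v <- raster@values
  cs <- raster@cellSize
  hdr <- c(
    paste("ncols", length(raster@xCenters)),
    paste("nrows", length(raster@yCenters)),
    paste("xllcorner", format(min(raster@xCenters) - cs / 2)),
    paste("yllcorner", format(min(raster@yCenters) - cs / 2)),
    paste("cellsize", format(cs)),
    paste("NODATA_value", nodata))
  v[is.na(v)] <- nodata
  lines <- vapply(rev(seq_along(raster@yCenters)), function(j)
    paste(format(v[, j], trim = TRUE), collapse = " "), "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write contours as GeoJSON
#'
#' @param contours list of polylines from [footprintContour()].
#' @param path output path.
#' @param properties optional list of properties attached to each
#'   feature.
#' @return `path`, invisibly.
#' @export
writeContourGeoJSON <- function(contours, path, properties = NULL) {
  features <- lapply(contours, function(m) {
    list(type = "Feature",
         properties = properties %||% setNames(list(), character(0)),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(m)),
                                              function(i) unname(m[i, ]))))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
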