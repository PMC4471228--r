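# Independent oracles the implementation is checked against. These stay
# deliberately separate from the package's code paths: the plateau
# oracle uses QR least squares over an exhaustive psi grid, the ROI
# oracle loops over pixels, and the ANCOVA oracle differences nested
# model RSS values.

# Exhaustive fine-grid plateau fit (pure R, .lm.fit QR solver).
bruteForcePlateau <- function(x, y, step = 0.01) {
  xs <- sort(x)
  n <- length(x)
  eps <- 1e-8 * (xs[n] - xs[1] + 1)
  grid <- seq(xs[2] + eps, xs[n - 1] - eps, by = step)
  sse <- vapply(grid, function(p) {
    u <- pmin(x - p, 0)
    sum(.lm.fit(cbind(1, u), y)$residuals^2)
  }, 0)
  k <- which.min(sse)
  list(psi = grid[k], sse = sse[k])
}

# Per-pixel loop ROI mean with its own even-odd crossing test.
naiveRoiMean <- function(intensity, roi) {
  v <- roiVertices(roi)
  vx <- v[, 1]; vy <- v[, 2]
  nv <- length(vx)
  jx <- vx[c(nv, seq_len(nv - 1))]; jy <- vy[c(nv, seq_len(nv - 1))]
  tot <- 0; cnt <- 0L
  for (cc in max(1, ceiling(min(vx))):min(ncol(intensity), floor(max(vx)))) {
    for (rr in max(1, ceiling(min(vy))):min(nrow(intensity), floor(max(vy)))) {
      crossing <- (vy > rr) != (jy > rr)
      xi <- jx + (rr - jy) * (vx - jx) / (vy - jy)
      if (sum(crossing & (cc < xi), na.rm = TRUE) %% 2 == 1) {
        tot <- tot + intensity[rr, cc]
        cnt <- cnt + 1L
      }
    }
  }
  list(mean = tot / cnt, count = cnt)
}

# Sequential sums of squares by nested-model RSS differences.
nestedSSOracle <- function(data, response, termLabels) {
  rss <- function(rhs) {
    f <- stats::as.formula(paste(response, "~", rhs))
    sum(stats::resid(stats::lm(f, data = data))^2)
  }
  prev <- rss("1")
  out <- numeric(length(termLabels))
  acc <- character(0)
  for (i in seq_along(termLabels)) {
    acc <- c(acc, termLabels[i])
    cur <- rss(paste(acc, collapse = " + "))
    out[i] <- prev - cur
    prev <- cur
  }
  out
}

# Small synthetic image scenario shared across image tests.
smallScenario <- function(targetGrey = 75, sloped = FALSE, textureSd = 0,
                          distortion = cbind(c(1, 1, 1), c(0, 0, 0)),
                          seed = 1, size = c(150, 120)) {
  srf <- if (sloped) seq(30, 60, length.out = size[2]) else 45
  imageScenario(targetGrey = targetGrey, surfaceRowProfile = srf,
                colourDistortion = distortion, textureSd = textureSd,
                imageSize = size, seed = seed)
}

# Measure a generated image end to end with the package pipeline.
measureSynthetic <- function(gen, topOffsetMm = 1, extentMm = 2,
                             mode = "polygon") {
  img <- gen$image; tr <- gen$truth
  I <- rgbToIntensity(img)
  srf <- detectSurface(I, columns = tr$analysisCols)
  roi <- makeRoi(srf, mode, topOffsetMm = topOffsetMm,
                 extentMm = extentMm, mmPerPx = tr$mmPerPx,
                 imageRows = nrow(I))
  meanIntensity(I, roi, tr$imageId)
}
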