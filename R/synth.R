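# Synthetic transect and survey generator. The generator is the ground
# truth backbone of the package: every downstream stage (AVS conversion,
# breakpoint fitting, ANCOVA, mapping) is tested against data produced
# here with known parameters.

#' Construct the generating model for a transect grey-value series
#'
#' The generating model is a linear rise to a plateau:
#' `grey(x) = background + slope * min(x - psi, 0) + N(0, sd^2)`, with `x`
#' the signed distance from the farm boundary in metres (negative inside
#' the farm). Defaults describe a paper-scale combined transect: plateau
#' (background) 93 grey values, mean grey inside the farm 61, breakpoint
#' 56 m outside the boundary, 182 points spanning -50 m to 200 m, and
#' noise SD 8.8 chosen so the fitted model explains about 69% of the
#' variance under this design.
#'
#' When `interiorSlope` is `NULL` it is derived so that the expected mean
#' grey over the inside-farm points (`x < 0`, even spacing) equals
#' `interiorMean`:
#' `slope = (background - interiorMean) / (psi - mean(x[x < 0]))`.
#'
#' @param backgroundGrey plateau grey level in \[0, 255\].
#' @param interiorMean target mean grey of inside-farm points; used only
#'   when `interiorSlope` is `NULL`.
#' @param breakpointM breakpoint, metres from the farm boundary.
#' @param noiseSd Gaussian noise SD in grey values (>= 0).
#' @param nPoints number of sampling points (>= 4).
#' @param xRangeM numeric(2), sampled signed-distance range in metres.
#' @param interiorSlope rise slope in grey per metre, or `NULL` to derive
#'   from `interiorMean`.
#' @return A [PlateauTruth-class] object.
#' @examples
#' plateauTruth()
#' plateauTruth(breakpointM = 35, interiorMean = 58, nPoints = 57)
#' @export
plateauTruth <- function(backgroundGrey = 93, interiorMean = 61,
                         breakpointM = 56, noiseSd = 8.8,
                         nPoints = 182, xRangeM = c(-50, 200),
                         interiorSlope = NULL) {
  nPoints <- as.integer(nPoints)
  xRangeM <- as.numeric(xRangeM)
  if (length(xRangeM) != 2L || !all(is.finite(xRangeM)) ||
      xRangeM[1] >= xRangeM[2])
    stop("xRangeM must be (min, max) with min < max")
  if (is.null(interiorSlope)) {
    if (interiorMean >= backgroundGrey)
      stop("interiorMean must be below backgroundGrey")
    x <- seq(xRangeM[1], xRangeM[2], length.out = nPoints)
    xin <- x[x < 0]
    if (!length(xin))
      stop("no inside-farm points (x < 0) to anchor interiorMean; ",
           "supply interiorSlope directly")
    interiorSlope <- (backgroundGrey - interiorMean) /
      (breakpointM - mean(xin))
  }
  new("PlateauTruth", backgroundGrey = backgroundGrey,
      interiorSlope = interiorSlope, breakpointM = breakpointM,
      noiseSd = noiseSd, nPoints = nPoints, xRangeM = as.numeric(xRangeM))
}

# Noise-free model value at signed distance x.
.plateauSignal <- function(truth, x) {
  truth@backgroundGrey +
    truth@interiorSlope * pmin(x - truth@breakpointM, 0)
}

#' Generate a synthetic transect dataset
#'
#' Draws `nPoints` signed distances over the truth's range (evenly spaced
#' or uniformly at random), evaluates the rise-to-plateau model, adds
#' Gaussian noise and clips to \[0, 255\]. The number of clipped values is
#' recorded in the `"clipped"` attribute; the generating truth in
#' `"truth"`.
#'
#' @param truth a [PlateauTruth-class] object.
#' @param seed integer seed; the caller's RNG state is preserved.
#' @param spacing `"even"` or `"random"` placement of the x values.
#' @param transect transect label stored in the output.
#' @param depth water depth: a single number or a function of `x`.
#' @return A `data.frame` (transect dataset) with columns `image_id`,
#'   `transect`, `distance_m`, `depth_m`, `grey_true`, `grey_obs`.
#' @examples
#' d <- generateTransect(plateauTruth(noiseSd = 0, nPoints = 10), seed = 1)
#' all(d$grey_obs[d$distance_m >= 56] == 93)
#' @export
generateTransect <- function(truth, seed = NULL,
                             spacing = c("even", "random"),
                             transect = "All", depth = 15) {
  stopifnot(is(truth, "PlateauTruth"))
  validObject(truth)
  spacing <- match.arg(spacing)
  r <- truth@xRangeM
  if (r[1] >= r[2]) stop("degenerate x range: min >= max")
  .withSeed(seed, {
    x <- if (spacing == "even")
      seq(r[1], r[2], length.out = truth@nPoints)
    else sort(runif(truth@nPoints, r[1], r[2]))
    mu <- .plateauSignal(truth, x)
    obs <- mu + rnorm(truth@nPoints, 0, truth@noiseSd)
    clipped <- sum(obs < 0 | obs > 255)
    obs <- .clip255(obs)
    dep <- if (is.function(depth)) depth(x) else rep(depth, length(x))
    out <- data.frame(
      image_id = sprintf("%s_%03d", transect, seq_along(x)),
      transect = transect,
      distance_m = x,
      depth_m = dep,
      grey_true = mu,
      grey_obs = obs,
      stringsAsFactors = FALSE
    )
    attr(out, "truth") <- truth
    attr(out, "clipped") <- clipped
    out
  })
}

#' Default paper-scale survey design
#'
#' Three transects (Shore, Mid, Channel) crossing the northern boundary
#' of a rectangular farm, with per-transect breakpoints 35, 71 and 19 m,
#' inside-farm mean greys 58, 59 and 70, sample sizes 57, 97 and 28
#' (182 points in total) and mean depths 13.6, 15.3 and 15.7 m.
#'
#' @return A list of per-transect specs consumed by [generateSurvey()]:
#'   each has `label`, `truth` ([PlateauTruth-class]), `start` and `end`
#'   local coordinates (m).
#' @export
defaultSurveySpecs <- function() {
  mk <- function(label, psi, interior, n, x0) {
    list(label = label,
         truth = plateauTruth(breakpointM = psi, interiorMean = interior,
                              nPoints = n),
         start = c(x0, -50), end = c(x0, 200))
  }
  list(mk("Shore", 35, 58, 57, 100),
       mk("Mid", 71, 59, 97, 300),
       mk("Channel", 19, 70, 28, 500))
}

#' Default demonstration farm boundary
#'
#' A 600 m x 400 m rectangular farm in local metric coordinates with its
#' northern edge along `y = 0` from `(0, 0)` to `(600, 0)`; transects of
#' [defaultSurveySpecs()] cross this edge.
#'
#' @return A [FarmBoundary-class] object.
#' @export
demoFarmBoundary <- function() {
  farmBoundary(rbind(c(0, -400), c(600, -400), c(600, 0), c(0, 0)),
               crs = "local")
}

# depth increasing from the shore-side transect to the channel, anchored
# at the per-transect mean depths
.defaultDepthModel <- function() {
  function(x, y) {
    stats::approx(c(100, 300, 500), c(13.6, 15.3, 15.7), xout = x,
                  rule = 2)$y
  }
}

#' Generate a synthetic multi-transect survey
#'
#' Places points evenly along each transect segment, computes signed
#' distances to the farm's northern boundary (negative inside the farm),
#' evaluates each transect's rise-to-plateau truth at those distances and
#' adds noise. Emulates a three-transect, 182-image survey design by
#' default.
#'
#' @param boundary a [FarmBoundary-class]; default [demoFarmBoundary()].
#' @param specs list of transect specs as in [defaultSurveySpecs()].
#' @param depthModel `function(x, y)` returning depth in metres; a
#'   constant function yields a constant depth column.
#' @param seed integer seed.
#' @return A `data.frame` with columns `image_id`, `transect`, `x_m`,
#'   `y_m`, `distance_m`, `depth_m`, `grey_true`, `grey_obs`; generating
#'   truths in the `"truths"` attribute, the boundary in `"boundary"`.
#' @examples
#' sv <- generateSurvey(seed = 1)
#' table(sv$transect)
#' @export
generateSurvey <- function(boundary = demoFarmBoundary(),
                           specs = defaultSurveySpecs(),
                           depthModel = .defaultDepthModel(),
                           seed = NULL) {
  stopifnot(is(boundary, "FarmBoundary"))
  .withSeed(seed, {
    parts <- lapply(specs, function(sp) {
      truth <- sp$truth
      stopifnot(is(truth, "PlateauTruth"))
      seg <- rbind(sp$start, sp$end)
      len <- sqrt(sum((seg[2, ] - seg[1, ])^2))
      if (len <= 0) stop("zero-length transect spec: ", sp$label)
      t <- seq(0, 1, length.out = truth@nPoints)
      pts <- cbind(seg[1, 1] + t * (seg[2, 1] - seg[1, 1]),
                   seg[1, 2] + t * (seg[2, 2] - seg[1, 2]))
      d <- signedDistance(pts, boundary)
      if (all(d < 0) || all(d > 0))
        warning("transect '", sp$label, "' lies entirely ",
                if (all(d < 0)) "inside" else "outside",
                " the farm; breakpoint may be unidentifiable")
      mu <- .plateauSignal(truth, d)
      obs <- .clip255(mu + rnorm(length(d), 0, truth@noiseSd))
      data.frame(
        image_id = sprintf("%s_%03d", sp$label, seq_along(d)),
        transect = sp$label,
        x_m = pts[, 1], y_m = pts[, 2],
        distance_m = d,
        depth_m = depthModel(pts[, 1], pts[, 2]),
        grey_true = mu, grey_obs = obs,
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    attr(out, "truths") <- setNames(
      lapply(specs, `[[`, "truth"), vapply(specs, `[[`, "", "label"))
    attr(out, "boundary") <- boundary
    out
  })
}

#' Write / read a transect or survey table
#'
#' Plain CSV with the documented schema (`image_id, transect, distance_m,
#' depth_m, grey_true, grey_obs`, plus `x_m`/`y_m` for surveys).
#'
#' @param data transect/survey `data.frame`.
#' @param path CSV path.
#' @return `writeTransectTable` returns `path` invisibly;
#'   `readTransectTable` the `data.frame`.
#' @export
writeTransectTable <- function(data, path) {
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTransectTable
#' @export
readTransectTable <- function(path) {
  if (!file.exists(path)) stop("no such table: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}
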