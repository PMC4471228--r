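# Plateau-constrained segmented regression. The model is
#   grey(x) = plateau + beta1 * min(x - psi, 0)
# i.e. a linear rise that meets a zero-slope background plateau at the
# breakpoint psi (the footprint boundary). The far-field slope is
# constrained to zero on the grounds that unaffected background sediment
# shows no long-distance colour trend. Estimation profiles psi: for each
# candidate the remaining parameters have a closed-form least squares
# solution; a coarse grid scan (seeded at psi0) plus dense-bracket
# golden-section refinement then yields the global SSE optimum, with the
# smallest psi kept among ties.

.plateauXY <- function(data) {
  if (is.numeric(data)) stop("fitPlateau expects a data.frame; see docs")
  x <- data[[.distanceColumn(data)]]
  y <- data[[.greyColumn(data)]]
  keep <- is.finite(x) & is.finite(y)
  list(x = x[keep], y = y[keep])
}

# shared non-convergence constructor
.plateauNonConverged <- function(x, y, psi0, profile, mirrored) {
  new("PlateauFit", psi = NA_real_, beta0 = NA_real_, beta1 = NA_real_,
      plateauLevel = NA_real_, r2 = NA_real_, sse = NA_real_,
      n = length(x), converged = FALSE, psi0Used = psi0,
      profile = profile, xRange = range(x), mirrored = mirrored)
}

#' Fit the rise-to-plateau segmented regression
#'
#' Estimates the footprint boundary as the breakpoint of a linear rise
#' meeting a zero-slope plateau. `psi` is profiled over a grid spanning
#' the identifiable interior of the x range (at least two points strictly
#' on each side), seeded with the starting value `psi0`, and refined by a
#' dense bracket scan plus golden-section search, so the optimum is
#' global on the profile rather than dependent on the start.
#'
#' The fit is declared non-converged (`isConverged(fit)` is `FALSE`,
#' estimates `NA`) when the breakpoint is unidentifiable: the SSE
#' profile is flat, the optimum sits at the boundary of the candidate
#' range, fewer than two points lie strictly on either side, or the
#' segmented terms do not improve on a flat mean line (profile F below
#' the 95% F quantile with 2 numerator degrees of freedom). A
#' non-convergent fit is never reported as a silent estimate.
#'
#' @param data transect `data.frame` with a distance column
#'   (`distance_m`) and a grey column (`grey_obs`/`grey`/`mean_grey`);
#'   at least 4 complete rows.
#' @param psi0 starting value for the profile scan (recorded in the
#'   fit; the global search makes the result start-independent).
#' @param gridN number of candidate breakpoints in the coarse scan.
#' @param refineTol absolute refinement tolerance for psi, metres.
#' @param mirror fit the mirrored orientation (plateau on the
#'   near-farm side, rise beyond the breakpoint).
#' @return A [PlateauFit-class] object.
#' @examples
#' d <- generateTransect(plateauTruth(noiseSd = 0, nPoints = 40), seed = 1)
#' fit <- fitPlateau(d)
#' psiEstimate(fit)  # 56
#' @export
fitPlateau <- function(data, psi0 = 100, gridN = 201, refineTol = 1e-4,
                       mirror = FALSE) {
  xy <- .plateauXY(data)
  x <- xy$x; y <- xy$y
  n <- length(x)
  if (n < 4) stop("need at least 4 complete observations")
  if (length(unique(x)) < 3) stop("x values nearly all equal; breakpoint ",
                                  "unidentifiable")
  xf <- if (mirror) -x else x
  p0 <- if (mirror) -psi0 else psi0
  xs <- sort(xf)
  eps <- 1e-8 * (xs[n] - xs[1] + 1)
  lo <- xs[2] + eps
  hi <- xs[n - 1] - eps
  emptyProf <- data.frame(psi = numeric(0), sse = numeric(0))
  if (!(lo < hi))
    return(.plateauNonConverged(x, y, psi0, emptyProf, mirror))
  fit <- .cppPlateauFit(xf, y, lo, hi, as.integer(gridN), p0, refineTol)
  prof <- .cppPlateauProfile(xf, y, seq(lo, hi, length.out = gridN))
  profile <- data.frame(psi = if (mirror) -prof$psi else prof$psi,
                        sse = prof$sse)
  sst <- sum((y - mean(y))^2)
  flat <- (max(prof$sse) - min(prof$sse)) <= 1e-12 * max(sst, 1)
  nl <- sum(xf < fit$psi); nr <- sum(xf > fit$psi)
  improvement <- sst - fit$sse
  fstat <- if (fit$sse > 0) (improvement / 2) / (fit$sse / (n - 3)) else Inf
  significant <- sst > 0 && fstat > qf(0.95, 2, n - 3)
  converged <- !fit$boundary && !flat && nl >= 2 && nr >= 2 && significant
  if (!converged)
    return(.plateauNonConverged(x, y, psi0, profile, mirror))
  psi <- if (mirror) -fit$psi else fit$psi
  beta1 <- if (mirror) -fit$beta1 else fit$beta1
  plateau <- fit$plateau
  new("PlateauFit",
      psi = psi, beta0 = plateau - beta1 * psi, beta1 = beta1,
      plateauLevel = plateau, r2 = 1 - fit$sse / sst, sse = fit$sse,
      n = n, converged = TRUE, psi0Used = psi0, profile = profile,
      xRange = range(x), mirrored = mirror)
}

#' Confidence interval for the breakpoint
#'
#' Two methods: case-resampling percentile bootstrap (default; each
#' resample is refitted by the same profiled search) and the delta
#' method from the linearised gap-variable parameterisation, in which
#' the model is refitted as `y ~ U + V` with `U = min(x - psi, 0)` and
#' the gap indicator `V = 1(x < psi)`, and
#' `SE(psi) = SE(gamma_V) / |beta1|`.
#'
#' @param data the transect `data.frame` the fit came from.
#' @param fit a converged [PlateauFit-class].
#' @param level confidence level.
#' @param method `"bootstrap"` or `"delta"`.
#' @param nBoot bootstrap replicates.
#' @param seed RNG seed for the resampling.
#' @param gridN coarse-grid size for bootstrap refits.
#' @return list of class `psiInterval`: `lower`, `upper`, `halfwidth`,
#'   `level`, `method`, and for the bootstrap `convergedFraction` and
#'   `reliable` (`FALSE` when more than 20% of refits did not
#'   converge).
#' @export
breakpointCI <- function(data, fit, level = 0.95,
                         method = c("bootstrap", "delta"),
                         nBoot = 1999, seed = NULL, gridN = 121) {
  method <- match.arg(method)
  stopifnot(is(fit, "PlateauFit"))
  if (!isConverged(fit)) stop("cannot compute a CI for a non-converged fit")
  xy <- .plateauXY(data)
  x <- xy$x; y <- xy$y
  n <- length(x)
  xf <- if (fit@mirrored) -x else x
  alpha <- 1 - level
  if (method == "delta") {
    psiF <- if (fit@mirrored) -fit@psi else fit@psi
    U <- pmin(xf - psiF, 0)
    V <- as.numeric(xf < psiF)
    m <- lm(y ~ U + V)
    seGamma <- sqrt(diag(vcov(m)))["V"]
    b1 <- abs(coef(m)["U"])
    sePsi <- unname(seGamma / b1)
    q <- qt(1 - alpha / 2, n - 3)
    ci <- fit@psi + c(-1, 1) * q * sePsi
    out <- list(lower = ci[1], upper = ci[2],
                halfwidth = q * sePsi, level = level, method = "delta",
                sePsi = sePsi)
  } else {
    idx <- .withSeed(seed,
      matrix(sample.int(n, n * nBoot, replace = TRUE), n, nBoot))
    bs <- .cppPlateauBoot(xf, y, idx, as.integer(gridN), 1e-3)
    psiB <- bs[, 1]
    conv <- bs[, 2] == 1 & is.finite(psiB)
    convFrac <- mean(conv)
    reliable <- convFrac >= 0.8
    if (!reliable)
      warning(sprintf(
        "bootstrap CI unreliable: only %.0f%% of refits converged",
        100 * convFrac))
    if (fit@mirrored) psiB <- -psiB
    qs <- quantile(psiB[conv], c(alpha / 2, 1 - alpha / 2), names = FALSE)
    out <- list(lower = qs[1], upper = qs[2],
                halfwidth = diff(qs) / 2, level = level,
                method = "bootstrap", nBoot = nBoot, seed = seed,
                convergedFraction = convFrac, reliable = reliable)
  }
  class(out) <- "psiInterval"
  out
}

#' @export
print.psiInterval <- function(x, ...) {
  cat(sprintf("%.0f%% %s CI for the breakpoint: [%.2f, %.2f] m (+/- %.2f)\n",
              100 * x$level, x$method, x$lower, x$upper, x$halfwidth))
  if (!is.null(x$reliable) && !x$reliable)
    cat(sprintf("  UNRELIABLE: only %.0f%% of bootstrap refits converged\n",
                100 * x$convergedFraction))
  invisible(x)
}

#' Starting-value sensitivity scan for the breakpoint
#'
#' Refits the plateau model from a grid of starting values (default 50
#' to 150 m in steps of 10) and reports whether all converged fits agree
#' on psi within `tol`. Starts outside the observed x range are flagged
#' invalid and skipped without affecting the others. Because the
#' estimator performs a global profile search, disagreement between
#' starts cannot arise from local optima; instead the SSE profile of the
#' first valid fit is scanned for near-tied local minima and a
#' `"multimodal"` attribute reports profile ambiguity (two competing
#' plateaus) rather than averaging over it.
#'
#' @param data transect `data.frame`.
#' @param psi0Grid starting values, metres.
#' @param tol agreement tolerance on psi, metres.
#' @param ... passed to [fitPlateau()].
#' @return `data.frame` with one row per start (`psi0`, `valid`,
#'   `converged`, `psi`, `sse`, `r2`); attributes `"agree"` and
#'   `"multimodal"`.
#' @export
psiSensitivity <- function(data, psi0Grid = seq(50, 150, by = 10),
                           tol = 0.1, ...) {
  xy <- .plateauXY(data)
  xr <- range(xy$x)
  rows <- lapply(psi0Grid, function(p0) {
    if (p0 < xr[1] || p0 > xr[2])
      return(data.frame(psi0 = p0, valid = FALSE, converged = NA,
                        psi = NA_real_, sse = NA_real_, r2 = NA_real_))
    f <- tryCatch(fitPlateau(data, psi0 = p0, ...), error = function(e) NULL)
    if (is.null(f))
      return(data.frame(psi0 = p0, valid = TRUE, converged = FALSE,
                        psi = NA_real_, sse = NA_real_, r2 = NA_real_))
    data.frame(psi0 = p0, valid = TRUE, converged = f@converged,
               psi = f@psi, sse = f@sse, r2 = f@r2)
  })
  out <- do.call(rbind, rows)
  ok <- out$valid & !is.na(out$converged) & out$converged
  attr(out, "agree") <- sum(ok) > 0 &&
    diff(range(out$psi[ok])) <= tol
  first <- which(ok)[1]
  attr(out, "multimodal") <- if (is.na(first)) NA else {
    f <- fitPlateau(data, psi0 = out$psi0[first], ...)
    .profileMultimodal(sseProfile(f))
  }
  out
}

# Competing breakpoints: a secondary local minimum of the SSE profile
# whose SSE is within 10% of the global minimum and separated from it by
# more than 5% of the psi range means two near-equally supported fits.
.profileMultimodal <- function(profile, tieRatio = 1.1, sepFrac = 0.05) {
  sse <- profile$sse; psi <- profile$psi
  if (length(sse) < 5) return(FALSE)
  if (max(sse) - min(sse) <= 0) return(FALSE)
  d <- diff(sse)
  loc <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  loc <- union(loc, which.min(sse))
  mn <- min(sse)
  near <- if (mn > 0) loc[sse[loc] <= tieRatio * mn]
          else loc[sse[loc] <= 1e-9]
  if (length(near) < 2) return(FALSE)
  any(dist(psi[near]) > sepFrac * diff(range(psi)))
}

#' Fit every transect and the combined dataset
#'
#' One plateau fit per transect plus a combined "All" fit, each with a
#' breakpoint confidence interval, summarised as a footprint-extent
#' table (`transect, extent_m, ci95_halfwidth_m, r2, n, converged`).
#' Transects whose fit fails or does not converge keep their row with
#' `converged = FALSE` and `NA` estimates.
#'
#' @param survey survey `data.frame` with a `transect` column.
#' @param psi0 starting value passed to [fitPlateau()].
#' @param ci compute confidence intervals.
#' @param ciMethod,nBoot,level,seed passed to [breakpointCI()].
#' @param ... further arguments to [fitPlateau()].
#' @return The summary `data.frame`; full [PlateauFit-class] objects in
#'   attribute `"fits"`.
#' @export
fitAllTransects <- function(survey, psi0 = 100, ci = TRUE,
                            ciMethod = "bootstrap", nBoot = 999,
                            level = 0.95, seed = NULL, ...) {
  if (!"transect" %in% names(survey)) stop("survey must have a transect column")
  labels <- unique(survey$transect)
  groups <- c(list(All = survey),
              setNames(lapply(labels, function(l)
                survey[survey$transect == l, , drop = FALSE]), labels))
  fits <- list()
  rows <- lapply(names(groups), function(nm) {
    d <- groups[[nm]]
    f <- tryCatch(fitPlateau(d, psi0 = psi0, ...), error = function(e) NULL)
    if (is.null(f) || !isConverged(f)) {
      fits[[nm]] <<- f
      return(data.frame(transect = nm, extent_m = NA_real_,
                        ci95_halfwidth_m = NA_real_, r2 = NA_real_,
                        n = nrow(d), converged = FALSE))
    }
    hw <- NA_real_
    if (ci) {
      interval <- tryCatch(
        breakpointCI(d, f, level = level, method = ciMethod,
                     nBoot = nBoot, seed = seed),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(interval)) {
        hw <- interval$halfwidth
        f@psiCI <- c(interval$lower, interval$upper)
        f@ciLevel <- level
      }
    }
    fits[[nm]] <<- f
    data.frame(transect = nm, extent_m = psiEstimate(f),
               ci95_halfwidth_m = hw, r2 = rSquared(f), n = f@n,
               converged = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Plot a plateau fit over its data
#'
#' @param data transect `data.frame`.
#' @param fit a [PlateauFit-class].
#' @param ... passed to `plot`.
#' @return invisibly, the fitted line coordinates.
#' @export
plotPlateau <- function(data, fit, ...) {
  xy <- .plateauXY(data)
  plot(xy$x, xy$y, xlab = "distance from farm boundary (m)",
       ylab = "grey value", ...)
  if (isConverged(fit)) {
    xs <- seq(min(xy$x), max(xy$x), length.out = 200)
    ys <- plateauLevel(fit) + riseSlope(fit) *
      (if (fit@mirrored) pmax(xs - psiEstimate(fit), 0)
       else pmin(xs - psiEstimate(fit), 0))
    lines(xs, ys, lwd = 2)
    abline(v = psiEstimate(fit), lty = 2)
  }
  invisible(NULL)
}
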