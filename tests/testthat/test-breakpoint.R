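# Plateau-constrained segmented regression: exact recovery, oracle
# agreement, equivariance, identifiability and confidence intervals.

test_that("noise-free data are recovered exactly", {
  for (seed in 1:6) {
    set.seed(seed)
    psi <- runif(1, 10, 150)
    plateau <- runif(1, 70, 120)
    # keep the rising limb above zero so clipping never distorts the model
    slope <- runif(1, 0.1, min(1, (plateau - 5) / (psi + 50)))
    tr <- plateauTruth(backgroundGrey = plateau, interiorSlope = slope,
                       breakpointM = psi, noiseSd = 0,
                       nPoints = sample(20:60, 1))
    f <- fitPlateau(generateTransect(tr, seed = seed))
    expect_true(isConverged(f))
    expect_lt(f@sse, 1e-9)
    expect_lt(abs(psiEstimate(f) - psi), 1e-3)
    expect_equal(plateauLevel(f), plateau, tolerance = 1e-6)
    expect_equal(rSquared(f), 1, tolerance = 1e-6)
  }
})

test_that("plateau identity beta0 + beta1 * psi holds exactly", {
  f <- fitPlateau(generateTransect(plateauTruth(nPoints = 80), seed = 2))
  expect_equal(f@beta0 + riseSlope(f) * psiEstimate(f), plateauLevel(f))
  expect_true(psiEstimate(f) >= f@xRange[1] && psiEstimate(f) <= f@xRange[2])
  expect_identical(f@psi0Used, 100)
})

test_that("pure-noise and flat series are flagged non-convergent", {
  set.seed(11)
  d <- data.frame(distance_m = seq(-50, 200, length.out = 100),
                  grey_obs = rnorm(100, 90, 5))
  f <- fitPlateau(d)
  expect_false(isConverged(f))
  expect_true(is.na(psiEstimate(f)))
  flat <- data.frame(distance_m = seq(0, 100, length.out = 20),
                     grey_obs = rep(90, 20))
  expect_false(isConverged(fitPlateau(flat)))
})

test_that("profiled search matches the exhaustive fine-grid oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(15:50, 1)
    tr <- plateauTruth(breakpointM = runif(1, 20, 120),
                       noiseSd = runif(1, 2, 10), nPoints = n)
    d <- generateTransect(tr, seed = seed, spacing = "random")
    f <- fitPlateau(d)
    bf <- bruteForcePlateau(d$distance_m, d$grey_obs)
    expect_lt(abs(psiEstimate(f) - bf$psi), 0.05)
    expect_lte(f@sse, bf$sse + 1e-6)
  }
})

test_that("plateau SSE never exceeds the flat-line SSE", {
  for (seed in 1:5) {
    d <- generateTransect(plateauTruth(noiseSd = 15, nPoints = 40),
                          seed = seed)
    f <- fitPlateau(d)
    sst <- sum((d$grey_obs - mean(d$grey_obs))^2)
    expect_lte(f@sse, sst)
    expect_gte(rSquared(f), 0)
    expect_lte(rSquared(f), 1)
  }
})

test_that("estimator is equivariant under x shifts and y scaling", {
  d <- generateTransect(plateauTruth(nPoints = 80), seed = 11)
  f <- fitPlateau(d)
  shifted <- d; shifted$distance_m <- shifted$distance_m + 37.5
  fs <- fitPlateau(shifted, psi0 = 137.5)
  expect_equal(psiEstimate(fs), psiEstimate(f) + 37.5, tolerance = 1e-6)
  scaled <- d; scaled$grey_obs <- scaled$grey_obs * 0.5
  fk <- fitPlateau(scaled)
  expect_equal(psiEstimate(fk), psiEstimate(f), tolerance = 1e-6)
  expect_equal(riseSlope(fk), riseSlope(f) * 0.5, tolerance = 1e-8)
  expect_equal(plateauLevel(fk), plateauLevel(f) * 0.5, tolerance = 1e-8)
  expect_equal(rSquared(fk), rSquared(f), tolerance = 1e-9)
})

test_that("mirrored orientation fits a plateau-then-rise series", {
  tr <- plateauTruth(noiseSd = 0, nPoints = 40)
  d <- generateTransect(tr, seed = 1)
  d$distance_m <- -d$distance_m  # plateau now on the left, rise after -56
  f <- fitPlateau(d, psi0 = -100, mirror = TRUE)
  expect_true(isConverged(f))
  expect_lt(abs(psiEstimate(f) + 56), 1e-3)
  expect_equal(plateauLevel(f), 93, tolerance = 1e-6)
})

test_that("zero-noise bootstrap intervals collapse to the truth", {
  d <- generateTransect(plateauTruth(noiseSd = 0, nPoints = 40), seed = 1)
  f <- fitPlateau(d)
  ci <- breakpointCI(d, f, nBoot = 199, seed = 4)
  expect_lt(ci$halfwidth, 0.05)
  expect_true(ci$lower <= 56 && 56 <= ci$upper)
})

test_that("bootstrap and delta intervals agree to within a factor of two", {
  # the case-resampling percentile interval is typically wider and
  # lumpier than the delta interval for breakpoints; same order of
  # magnitude is the realistic cross-method check
  d <- generateTransect(plateauTruth(), seed = 301)
  f <- fitPlateau(d)
  hb <- breakpointCI(d, f, nBoot = 499, seed = 1)$halfwidth
  hd <- breakpointCI(d, f, method = "delta")$halfwidth
  expect_gt(hb / hd, 0.5)
  expect_lt(hb / hd, 2)
  expect_true(hd > 5 && hd < 25)  # paper-scale uncertainty, metres
})

test_that("CIs are refused for non-converged fits", {
  set.seed(12)
  d <- data.frame(distance_m = seq(-50, 200, length.out = 60),
                  grey_obs = rnorm(60, 90, 5))
  f <- fitPlateau(d)
  expect_error(breakpointCI(d, f), "non-converged")
})

test_that("starting values do not bias the global profile optimum", {
  d <- generateTransect(plateauTruth(nPoints = 120), seed = 15)
  s <- psiSensitivity(d)
  expect_identical(nrow(s), 11L)
  expect_true(all(s$valid))
  expect_true(attr(s, "agree"))
  expect_false(attr(s, "multimodal"))
  expect_lt(diff(range(s$psi)), 0.1)
})

test_that("starts outside the x range are flagged without affecting others", {
  tr <- plateauTruth(breakpointM = 30, xRangeM = c(-50, 80), nPoints = 60)
  d <- generateTransect(tr, seed = 3)
  s <- psiSensitivity(d)  # grid 50..150; starts above 80 are invalid
  expect_true(all(!s$valid[s$psi0 > 80]))
  expect_true(all(s$valid[s$psi0 <= 80]))
  expect_true(attr(s, "agree"))
})

test_that("competing plateaus are reported as multimodal, not averaged", {
  x <- seq(-50, 200, length.out = 150)
  set.seed(5)
  y <- ifelse(x < 0, 93 + 0.3 * x,
              ifelse(x < 170, 93, ifelse(x < 190, 55, 93))) +
    rnorm(150, 0, 1)
  d <- data.frame(distance_m = x, grey_obs = pmin(pmax(y, 0), 255))
  s <- suppressWarnings(psiSensitivity(d))
  expect_true(attr(s, "multimodal"))
})

test_that("per-transect fits recover the survey ground truths", {
  est <- matrix(NA_real_, 5, 4,
                dimnames = list(NULL, c("All", "Shore", "Mid", "Channel")))
  for (i in 1:5) {
    sv <- generateSurvey(seed = 600 + i)
    tab <- fitAllTransects(sv, ci = FALSE)
    est[i, tab$transect] <- tab$extent_m
  }
  means <- colMeans(est)
  expect_lt(abs(means["Shore"] - 35), 10)
  expect_lt(abs(means["Mid"] - 71), 10)
  expect_lt(abs(means["Channel"] - 19), 15)  # n = 28: widest sampling noise
  # combined estimate sits between the per-transect extremes
  expect_true(all(est[, "All"] > apply(est[, 2:4], 1, min) &
                  est[, "All"] < apply(est[, 2:4], 1, max)))
})

test_that("single-transect surveys give matching combined and transect rows", {
  d <- generateTransect(plateauTruth(nPoints = 60), seed = 8,
                        transect = "Only")
  tab <- fitAllTransects(d, ci = FALSE)
  expect_identical(tab$transect, c("All", "Only"))
  expect_equal(tab$extent_m[1], tab$extent_m[2])
  expect_equal(tab$r2[1], tab$r2[2])
})

test_that("transects without interior points are flagged, others fitted", {
  good <- generateTransect(plateauTruth(nPoints = 60), seed = 2,
                           transect = "Good")
  flatTail <- good[good$distance_m > 100, ]
  flatTail$transect <- "Flat"
  sv <- rbind(good, flatTail)
  tab <- fitAllTransects(sv, ci = FALSE)
  expect_false(tab$converged[tab$transect == "Flat"])
  expect_true(tab$converged[tab$transect == "Good"])
  expect_true(is.na(tab$extent_m[tab$transect == "Flat"]))
})
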