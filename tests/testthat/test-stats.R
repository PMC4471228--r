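# ANCOVA (sequential SS), Tukey-Kramer contrasts and the paired t-test.

test_that("sequential sums of squares equal nested-model RSS differences", {
  set.seed(20)
  for (rep in 1:6) {
    n <- 60
    d <- data.frame(
      distance_m = runif(n, -50, 200),
      depth_m = runif(n, 12, 16),
      transect = sample(c("Shore", "Mid", "Channel"), n, replace = TRUE),
      grey_obs = rnorm(n, 80, 10))
    d$grey_obs <- d$grey_obs + 0.05 * d$distance_m +
      2 * (d$transect == "Channel")
    forms <- list(c("distance_m", "transect"),
                  c("distance_m", "transect", "depth_m"))
    for (terms in forms) {
      tab <- ancova(d, terms = terms)
      labels <- tab$term[tab$term != "Residuals"]
      oracle <- nestedSSOracle(d, "grey_obs", labels)
      got <- tab$sum_sq[tab$term != "Residuals"]
      expect_equal(got, oracle, tolerance = 1e-8)
    }
    # full factorial with interactions
    tabF <- ancova(d, terms = c("distance_m", "transect", "depth_m"),
                   fullFactorial = TRUE)
    labs <- tabF$term[tabF$term != "Residuals"]
    expect_identical(labs, c("distance_m", "transect", "depth_m",
                             "distance_m:transect", "distance_m:depth_m",
                             "transect:depth_m",
                             "distance_m:transect:depth_m"))
    oracleF <- nestedSSOracle(d, "grey_obs", labs)
    expect_equal(tabF$sum_sq[seq_along(labs)], oracleF, tolerance = 1e-8)
  }
})

test_that("sums of squares are conserved", {
  sv <- generateSurvey(seed = 4)
  tab <- ancova(sv, terms = c("distance_m", "transect"))
  sst <- sum((sv$grey_obs - mean(sv$grey_obs))^2)
  expect_equal(sum(tab$sum_sq), sst)
  expect_equal(sum(tab$df), nrow(sv) - 1)
  expect_true(all(tab$sum_sq >= 0))
})

test_that("orthogonal null data give zero F", {
  d <- data.frame(grey = c(1, 3, 2, 2, 3, 1),
                  x = c(1, 2, 3, 1, 2, 3),
                  g = rep(c("A", "B"), each = 3))
  tab <- ancova(d, response = "grey", terms = c("x", "g"))
  expect_equal(tab$f_value[1:2], c(0, 0), tolerance = 1e-12)
  expect_equal(tab$p_value[1:2], c(1, 1), tolerance = 1e-12)
})

test_that("rank-deficient designs are reported with the aliased term", {
  d <- data.frame(grey = rnorm(20), a = rep(c("x", "y"), 10))
  d$b <- d$a  # perfectly aliased copy
  expect_error(ancova(d, response = "grey", terms = c("a", "b")),
               "aliased")
})

test_that("the survey reproduces the inside/outside contrast pattern", {
  sv <- generateSurvey(seed = 2)
  inside <- ancova(sv[sv$distance_m < 0, ],
                   terms = c("distance_m", "transect"))
  outside <- ancova(sv[sv$distance_m > 0, ],
                    terms = c("distance_m", "transect"))
  pIn <- inside$p_value[inside$term == "transect"]
  pOut <- outside$p_value[outside$term == "transect"]
  expect_lt(pIn, 0.05)
  expect_gt(pOut, 0.05)
  tk <- tukeyContrasts(inside, "transect")
  # interior greys Shore 58, Mid 59 darker than Channel 70:
  # both separate from Channel, Shore and Mid do not separate
  expect_lt(tk$p_adj[tk$pair == "Mid - Channel"], 0.05)
  expect_lt(tk$p_adj[tk$pair == "Shore - Channel"], 0.05)
  expect_gt(tk$p_adj[tk$pair == "Shore - Mid"], 0.05)
  am <- attr(tk, "adjustedMeans")
  expect_true(all(am[c("Shore", "Mid")] < am["Channel"]))
})

test_that("a far-shifted group separates while identical groups do not", {
  set.seed(30)
  d <- data.frame(y = c(rnorm(20, 0), rnorm(20, 0), rnorm(20, 10)),
                  g = rep(c("a", "b", "c"), each = 20))
  tk <- tukeyContrasts(lm(y ~ g, data = d), "g")
  expect_gt(tk$p_adj[tk$pair == "b - a"], 0.05)
  expect_lt(tk$p_adj[tk$pair == "c - a"], 1e-6)
  expect_lt(tk$p_adj[tk$pair == "c - b"], 1e-6)
})

test_that("two-level Tukey equals the coefficient t-test", {
  set.seed(31)
  d <- data.frame(y = rnorm(30), x = rnorm(30),
                  g = rep(c("a", "b"), 15))
  m <- lm(y ~ x + g, data = d)
  tk <- tukeyContrasts(m, "g")
  pT <- summary(m)$coefficients["gb", "Pr(>|t|)"]
  expect_equal(tk$p_adj, pT, tolerance = 1e-10)
})

test_that("Tukey contrasts agree with TukeyHSD on balanced one-way data", {
  set.seed(32)
  d <- data.frame(y = rnorm(45, rep(c(0, 1, 3), each = 15)),
                  g = factor(rep(c("a", "b", "c"), each = 15)))
  tk <- tukeyContrasts(lm(y ~ g, data = d), "g")
  hsd <- TukeyHSD(aov(y ~ g, data = d))$g
  key <- gsub(" ", "", tk$pair)
  expect_equal(tk$p_adj, unname(hsd[key, "p adj"]), tolerance = 1e-8)
  expect_equal(tk$diff, unname(hsd[key, "diff"]), tolerance = 1e-10)
  expect_equal(tk$lwr, unname(hsd[key, "lwr"]), tolerance = 1e-8)
})

test_that("permuting factor labels permutes Tukey pairs consistently", {
  set.seed(33)
  d <- data.frame(y = rnorm(60), x = rnorm(60),
                  g = rep(c("a", "b", "c"), 20))
  tk1 <- tukeyContrasts(lm(y ~ x + g, data = d), "g")
  d2 <- d
  d2$g <- factor(d2$g, levels = c("c", "b", "a"))
  tk2 <- tukeyContrasts(lm(y ~ x + g, data = d2), "g")
  p1 <- setNames(tk1$p_adj, gsub(" ", "", tk1$pair))
  for (pr in names(p1)) {
    parts <- strsplit(pr, "-")[[1]]
    rev <- paste0(parts[2], "-", parts[1])
    key <- gsub(" ", "", tk2$pair)
    expect_equal(unname(p1[pr]),
                 tk2$p_adj[key == pr | key == rev], tolerance = 1e-10)
  }
})

test_that("ANCOVA p-values are uniform under the null", {
  set.seed(34)
  p <- vapply(1:1000, function(i) {
    d <- data.frame(y = rnorm(60), x = rnorm(60),
                    g = rep(c("a", "b", "c"), 20))
    tab <- ancova(d, response = "y", terms = c("x", "g"))
    tab$p_value[tab$term == "g"]
  }, 0)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("paired t matches the textbook formula", {
  set.seed(35)
  a <- rnorm(40, 80, 6); b <- a + rnorm(40, 0.2, 1.5)
  res <- pairedT(a, b)
  d <- a - b
  tRef <- mean(d) / (sd(d) / sqrt(length(d)))
  pRef <- 2 * pt(-abs(tRef), length(d) - 1)
  expect_equal(res$t, tRef, tolerance = 1e-10)
  expect_equal(res$p, pRef, tolerance = 1e-10)
  expect_equal(res$df, 39)
})

test_that("degenerate paired inputs behave as defined", {
  x <- c(1, 2, 3, 4)
  same <- pairedT(x, x)
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  expect_error(pairedT(c(1, 2, 3), c(2, 3, 4)), "zero variance")
  expect_error(pairedT(1, 1:2), "equal length")
})
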