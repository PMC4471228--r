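# Comparison statistics: sequential (Type I) ANCOVA, Tukey-Kramer
# post-hoc contrasts on covariate-adjusted means, and the paired t-test
# used to compare the rectangle and polygon ROI methods.

#' ANCOVA with sequential (Type I) sums of squares
#'
#' Ordinary least squares with treatment contrasts; terms enter the
#' model in the order given, and each term's sum of squares is the
#' reduction in residual SS when it is added to the terms before it
#' (sequential ANOVA). Character terms are coerced to factors; numeric
#' terms are treated as continuous covariates. The canonical transect
#' models are `grey ~ distance + transect` and the full factorial
#' `grey ~ distance * transect * depth`.
#'
#' @param data `data.frame` containing response and terms.
#' @param response response column name (default the table's grey
#'   column).
#' @param terms character vector of model terms in entry order;
#'   interaction terms like `"distance_m:transect"` are allowed, or set
#'   `fullFactorial = TRUE` to expand all interactions.
#' @param fullFactorial expand `terms` to the full factorial.
#' @return `data.frame` of class `spiAncova` with rows per term plus
#'   `Residuals`: columns `term`, `df`, `sum_sq`, `mean_sq`,
#'   `f_value`, `p_value`; model R^2 in attribute `"r.squared"`, the
#'   underlying `lm` fit in `"model"`.
#' @examples
#' sv <- generateSurvey(seed = 1)
#' ancova(sv, terms = c("distance_m", "transect"))
#' @export
ancova <- function(data, response = NULL,
                   terms = c("distance_m", "transect"),
                   fullFactorial = FALSE) {
  if (is.null(response)) response <- .greyColumn(data)
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  missing <- setdiff(c(response, vars), names(data))
  if (length(missing))
    stop("columns not in data: ", paste(missing, collapse = ", "))
  d <- data[, c(response, vars)]
  for (v in vars) {
    if (is.character(d[[v]])) d[[v]] <- factor(d[[v]])
    if (is.factor(d[[v]]) && nlevels(droplevels(d[[v]])) < 2)
      stop("factor '", v, "' has fewer than 2 observed levels")
  }
  d <- d[complete.cases(d), , drop = FALSE]
  rhs <- if (fullFactorial) paste(terms, collapse = " * ")
         else paste(terms, collapse = " + ")
  form <- stats::as.formula(paste(response, "~", rhs))
  m <- lm(form, data = d)
  X <- model.matrix(m)
  if (m$rank < ncol(X)) {
    aliased <- names(which(is.na(coef(m))))
    stop("rank-deficient design; aliased: ",
         paste(aliased, collapse = ", "))
  }
  if (nrow(d) <= length(coef(m)))
    stop("n must exceed the number of model coefficients")
  a <- anova(m)
  out <- data.frame(term = rownames(a), df = a$Df, sum_sq = a$`Sum Sq`,
                    mean_sq = a$`Mean Sq`, f_value = a$`F value`,
                    p_value = a$`Pr(>F)`, stringsAsFactors = FALSE)
  attr(out, "r.squared") <- summary(m)$r.squared
  attr(out, "model") <- m
  class(out) <- c("spiAncova", "data.frame")
  out
}

#' @export
print.spiAncova <- function(x, ...) {
  cat("Sequential (Type I) ANCOVA, R^2 =",
      format(attr(x, "r.squared"), digits = 3), "\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Tukey-Kramer contrasts on covariate-adjusted means
#'
#' Simultaneous pairwise comparisons of factor-level means adjusted to
#' the covariate means, using the studentized range distribution with
#' the model's residual degrees of freedom (Tukey-Kramer, valid for
#' unbalanced designs). For a two-level factor the adjusted p-value
#' equals the ordinary t-test p-value.
#'
#' @param model an `lm` fit or an `spiAncova` table.
#' @param factor name of the factor to compare.
#' @param level simultaneous confidence level.
#' @return `data.frame` with columns `pair`, `diff` (adjusted mean
#'   difference), `lwr`, `upr` (simultaneous CI) and `p_adj`; adjusted
#'   means in attribute `"adjustedMeans"`.
#' @export
tukeyContrasts <- function(model, factor, level = 0.95) {
  if (inherits(model, "spiAncova")) model <- attr(model, "model")
  stopifnot(inherits(model, "lm"))
  mf <- stats::model.frame(model)
  if (!factor %in% names(mf)) stop("'", factor, "' is not in the model")
  f <- mf[[factor]]
  levs <- model$xlevels[[factor]]
  if (is.null(levs)) {
    if (!is.factor(f)) stop("'", factor, "' is not a factor in the model")
    levs <- levels(droplevels(f))
  }
  k <- length(levs)
  if (k < 2) stop("factor '", factor, "' has fewer than 2 observed levels")
  # design rows at covariate means / modal handling: covariates at their
  # means, the focus factor at each level, other factors at their first level
  base <- mf[1, , drop = FALSE]
  for (v in names(mf)) {
    if (v == factor) next
    if (is.numeric(mf[[v]])) base[[v]] <- mean(mf[[v]])
  }
  newdata <- base[rep(1, k), , drop = FALSE]
  flev <- if (is.factor(f)) levels(f) else levs
  newdata[[factor]] <- base::factor(levs, levels = flev)
  tt <- stats::delete.response(terms(model))
  xlev <- model$xlevels
  if (is.null(xlev)) xlev <- stats::.getXlevels(tt, mf)
  X <- model.matrix(tt, newdata, xlev = xlev)
  beta <- coef(model)
  V <- vcov(model)
  adj <- drop(X %*% beta)
  dfres <- df.residual(model)
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    ctr <- X[ij[2], ] - X[ij[1], ]
    est <- sum(ctr * beta)
    se <- sqrt(drop(t(ctr) %*% V %*% ctr))
    q <- abs(est) / se * sqrt(2)
    p <- ptukey(q, nmeans = k, df = dfres, lower.tail = FALSE)
    hw <- qtukey(level, nmeans = k, df = dfres) / sqrt(2) * se
    c(est = est, lwr = est - hw, upr = est + hw, p = p)
  })
  out <- data.frame(
    pair = apply(pairs, 2, function(ij) paste(levs[ij[2]], "-", levs[ij[1]])),
    diff = res["est", ], lwr = res["lwr", ], upr = res["upr", ],
    p_adj = res["p", ], stringsAsFactors = FALSE)
  attr(out, "adjustedMeans") <- setNames(adj, levs)
  attr(out, "level") <- level
  out
}

#' Paired-samples t-test
#'
#' Classical paired t statistic with `df = n - 1` and a two-sided
#' p-value, as used to show that rectangle and polygon ROI selections
#' yield indistinguishable mean greys.
#'
#' @param a,b paired measurement vectors of equal length (>= 2),
#'   pairwise complete.
#' @return list with `t`, `df`, `p`.
#' @examples
#' pairedT(c(1, 2, 3, 5), c(1.1, 2.2, 2.4, 5.6))
#' @export
pairedT <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2) stop("need at least 2 complete pairs")
  if (sd(a - b) == 0) {
    if (all(a == b))  # literally identical measurements: no difference
      return(list(t = 0, df = length(a) - 1, p = 1))
    stop("zero variance of the pairwise differences; t is undefined")
  }
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
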