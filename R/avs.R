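# Grey value -> acid volatile sulfide (AVS) conversion.

#' Construct a grey-to-AVS calibration
#'
#' Site-specific quadratic `AVS = a * grey^2 + b * grey + c` in umol per
#' gram sediment. Defaults are the published Awakiriapa Bay long-line
#' mussel farm coefficients
#' (`AVS = 0.0024 * GREY^2 - 0.5249 * GREY + 28.392`). The grey range
#' over which that calibration interpolates was published only
#' graphically, so `validGreyRange` is a package choice (55--105 by
#' default) and should be set from the calibration data when available.
#' `ciHalfwidth` is the mean 95% individual confidence interval of the
#' calibration (0.5 umol/g for the default equation): negative predicted
#' concentrations within it are consistent with true AVS near zero.
#'
#' @param a,b,c quadratic coefficients.
#' @param validGreyRange numeric(2) calibrated grey interval.
#' @param ciHalfwidth mean 95% individual CI, umol/g.
#' @return An [AVSCalibration-class] object.
#' @export
avsCalibration <- function(a = 0.0024, b = -0.5249, c = 28.392,
                           validGreyRange = c(55, 105),
                           ciHalfwidth = 0.5) {
  new("AVSCalibration", a = a, b = b, c = c,
      validGreyRange = as.numeric(validGreyRange),
      ciHalfwidth = ciHalfwidth)
}

#' Convert grey values to AVS concentration estimates
#'
#' Evaluates the quadratic calibration at each grey value. Values outside
#' the calibrated grey range are still converted but flagged as
#' extrapolated (`in_range = FALSE`). Negative estimates are flagged,
#' never clamped: within the calibration's individual CI they are
#' consistent with a true concentration at or near 0 umol/g. The
#' polynomial is decreasing up to its vertex at `-b/(2a)` (about 109
#' grey values for the default), so darker sediment maps to higher AVS
#' over the working range.
#'
#' @param grey numeric grey values in \[0, 255\].
#' @param cal an [AVSCalibration-class].
#' @return `data.frame` with columns `grey`, `avs` (umol/g), `in_range`,
#'   `negative`.
#' @examples
#' greyToAvs(c(0, 61, 93, 100))
#' @export
greyToAvs <- function(grey, cal = avsCalibration()) {
  if (!is.numeric(grey) || anyNA(grey) || any(!is.finite(grey)))
    stop("grey values must be finite numbers")
  if (any(grey < 0 | grey > 255)) stop("grey values must lie in [0, 255]")
  v <- cal@a * grey^2 + cal@b * grey + cal@c
  data.frame(grey = grey, avs = v,
             in_range = grey >= cal@validGreyRange[1] &
                        grey <= cal@validGreyRange[2],
             negative = v < 0)
}

#' Append AVS estimates to a measurement or transect table
#'
#' Adds `avs`, `avs_in_range` and `avs_negative` columns computed from
#' the table's grey column (`grey_obs`, `grey`, `mean_grey` or
#' `grey_value`, whichever is present). Counts of extrapolated and
#' negative rows are reported in attributes `"n_out_of_range"` and
#' `"n_negative"` and via a message.
#'
#' @param measurements `data.frame` with a grey column.
#' @param cal an [AVSCalibration-class].
#' @param quiet suppress the count message.
#' @return The augmented `data.frame`.
#' @export
convertTable <- function(measurements, cal = avsCalibration(),
                         quiet = FALSE) {
  if (!is.data.frame(measurements)) stop("measurements must be a data.frame")
  if (nrow(measurements) == 0) {
    out <- measurements
    out$avs <- numeric(0); out$avs_in_range <- logical(0)
    out$avs_negative <- logical(0)
    attr(out, "n_out_of_range") <- 0L
    attr(out, "n_negative") <- 0L
    return(out)
  }
  gcol <- .greyColumn(measurements)
  est <- greyToAvs(measurements[[gcol]], cal)
  out <- measurements
  out$avs <- est$avs
  out$avs_in_range <- est$in_range
  out$avs_negative <- est$negative
  attr(out, "n_out_of_range") <- sum(!est$in_range)
  attr(out, "n_negative") <- sum(est$negative)
  if (!quiet)
    message(sum(!est$in_range), " of ", nrow(out),
            " rows outside the calibrated grey range (extrapolated); ",
            sum(est$negative), " negative AVS estimates")
  out
}
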