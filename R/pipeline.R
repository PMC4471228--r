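# End-to-end orchestration: survey table -> AVS conversion -> breakpoint
# fits -> ANCOVA -> footprint raster and contour, with a reproducibility
# manifest. Each stage failure aborts with the stage name.

#' Default run configuration
#'
#' @param outputDir directory for run outputs (created if needed).
#' @param seed master seed: survey simulation and bootstrap resampling
#'   both derive from it.
#' @return Nested configuration list; override entries before passing
#'   to [runSurvey()]. Keys: `seed`, `outputDir`, `survey$csv` (path to
#'   a survey table, or `NULL` to simulate the default synthetic
#'   survey), `boundary$csv` (CSV of polygon vertices, or `NULL` for
#'   the built-in demo farm), `avs` (`a`, `b`, `c`, `greyLo`, `greyHi`),
#'   `fit` (`psi0`, `ciMethod`, `nBoot`, `level`), `map` (`cellSize`,
#'   `bandwidth`, `power`, `maxDist`, `method`, `contourThreshold`,
#'   `NULL` = midway between fitted plateau and inside-farm mean).
#' @export
defaultRunConfig <- function(outputDir = tempfile("spiRun"), seed = 1L) {
  list(
    seed = as.integer(seed),
    outputDir = outputDir,
    survey = list(csv = NULL),
    boundary = list(csv = NULL),
    avs = list(a = 0.0024, b = -0.5249, c = 28.392,
               greyLo = 55, greyHi = 105),
    fit = list(psi0 = 100, ciMethod = "bootstrap", nBoot = 999,
               level = 0.95),
    map = list(cellSize = 5, bandwidth = 25, power = 2, maxDist = 100,
               method = "localPolynomial", contourThreshold = NULL)
  )
}

#' Validate a run configuration
#'
#' Checks paths and parameter sanity before any computation; errors are
#' validation errors naming the offending key.
#'
#' @param config configuration list (see [defaultRunConfig()]) or path
#'   to a YAML file of the same structure.
#' @return The normalised configuration list, invisibly valid.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("validation error: config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  config <- utils::modifyList(defaultRunConfig(), config)
  config$seed <- as.integer(config$seed)
  config$fit$nBoot <- as.integer(config$fit$nBoot)
  for (key in c("survey", "boundary")) {
    p <- config[[key]]$csv
    if (!is.null(p) && !file.exists(p))
      stop("validation error: ", key, " file not found: ", p)
  }
  if (!config$fit$ciMethod %in% c("bootstrap", "delta"))
    stop("validation error: fit$ciMethod must be bootstrap or delta")
  if (config$map$cellSize <= 0)
    stop("validation error: map$cellSize must be > 0")
  config
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full footprint analysis
#'
#' Loads or simulates a survey, converts grey values to AVS estimates,
#' fits the plateau model per transect and combined, runs the three
#' ANCOVA strata (overall, inside farm, outside farm) with Tukey
#' contrasts where the transect effect is significant (p < 0.05),
#' interpolates the footprint raster and extracts its contour, and
#' writes everything plus a manifest (package version, config hash,
#' seeds) into the output directory.
#'
#' @param config configuration list or YAML path; see
#'   [defaultRunConfig()].
#' @return The output directory path, invisibly; the run's main objects
#'   are returned in the `"results"` attribute.
#' @examples
#' \donttest{
#' dir <- runSurvey(defaultRunConfig(seed = 1))
#' list.files(dir)
#' }
#' @export
runSurvey <- function(config = defaultRunConfig()) {
  config <- .stage("validate", validateRunConfig(config))
  out <- config$outputDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  boundary <- .stage("boundary", {
    if (is.null(config$boundary$csv)) demoFarmBoundary()
    else farmBoundary(read.csv(config$boundary$csv))
  })
  survey <- .stage("survey", {
    if (is.null(config$survey$csv))
      generateSurvey(boundary = boundary, seed = config$seed)
    else readTransectTable(config$survey$csv)
  })
  writeTransectTable(survey, file.path(out, "survey.csv"))

  cal <- avsCalibration(a = config$avs$a, b = config$avs$b,
                        c = config$avs$c,
                        validGreyRange = c(config$avs$greyLo,
                                           config$avs$greyHi))
  avsTab <- .stage("avs", convertTable(survey, cal, quiet = TRUE))
  write.csv(avsTab, file.path(out, "avs_table.csv"), row.names = FALSE)

  fitTab <- .stage("fit", fitAllTransects(
    survey, psi0 = config$fit$psi0, ciMethod = config$fit$ciMethod,
    nBoot = config$fit$nBoot, level = config$fit$level,
    seed = config$seed))
  write.csv(fitTab, file.path(out, "fit_summary.csv"), row.names = FALSE)
  fits <- attr(fitTab, "fits")
  jsonlite::write_json(
    lapply(fits, function(f) {
      if (is.null(f)) return(list(converged = FALSE))
      list(converged = isConverged(f), psi = psiEstimate(f),
           psi_ci = psiCI(f), beta1 = riseSlope(f),
           plateau = plateauLevel(f), r2 = rSquared(f), sse = f@sse,
           n = f@n, psi0 = f@psi0Used,
           sse_profile = sseProfile(f)[seq(1, max(1, nrow(sseProfile(f))),
                                           by = 4), ])
    }),
    file.path(out, "fits.json"), auto_unbox = TRUE, digits = NA,
    na = "null")

  anc <- .stage("stats", {
    strata <- list(
      overall = survey,
      inside = survey[survey$distance_m < 0, ],
      outside = survey[survey$distance_m > 0, ])
    lapply(names(strata), function(nm) {
      tab <- ancova(strata[[nm]], terms = c("distance_m", "transect"))
      write.csv(as.data.frame(tab),
                file.path(out, paste0("ancova_", nm, ".csv")),
                row.names = FALSE)
      pTr <- tab$p_value[tab$term == "transect"]
      if (length(pTr) && is.finite(pTr) && pTr < 0.05) {
        tk <- tukeyContrasts(tab, "transect")
        write.csv(tk, file.path(out, paste0("tukey_", nm, ".csv")),
                  row.names = FALSE)
      }
      tab
    })
  })

  ras <- .stage("map", {
    if (!all(c("x_m", "y_m") %in% names(survey)))
      stop("survey lacks x_m/y_m positions; mapping skipped")
    interpolateGrey(
      survey[, c("x_m", "y_m")], survey[[.greyColumn(survey)]],
      gridSpec = list(cellSize = config$map$cellSize),
      method = config$map$method,
      params = config$map[c("bandwidth", "power", "maxDist")])
  })
  writeAsciiGrid(ras, file.path(out, "raster.asc"))

  contour <- .stage("contour", {
    thr <- config$map$contourThreshold
    if (is.null(thr)) {
      allFit <- fits[["All"]]
      insideMean <- mean(survey[[.greyColumn(survey)]][survey$distance_m < 0])
      thr <- if (!is.null(allFit) && isConverged(allFit))
        (plateauLevel(allFit) + insideMean) / 2
      else mean(range(rasterValues(ras), na.rm = TRUE))
    }
    footprintContour(ras, thr)
  })
  writeContourGeoJSON(contour, file.path(out, "contour.geojson"))

  cfgFile <- file.path(out, "config.yaml")
  yaml::write_yaml(config, cfgFile)
  manifest <- list(
    package = "spiFootprint",
    version = as.character(packageVersion("spiFootprint")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfgFile)),
    created = format(Sys.time(), tz = "UTC"),
    outputs = list.files(out))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  attr(out, "results") <- list(survey = survey, avs = avsTab,
                               fits = fitTab, ancova = anc,
                               raster = ras, contour = contour)
  invisible(out)
}
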