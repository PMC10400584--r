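# End-to-end pipeline: configuration, synthetic-input materialisation,
# and the staged exposure -> aggregation -> impact -> report run.

#' Default pipeline configuration
#'
#' The defaults are the package's study conditions: a 36 x 24 grid of
#' 12 km cells, a 9 x 6 county tessellation (unsnapped, 2 withheld
#' records), a 92-day May-July window accumulated over all 24 hours at a
#' 0.04 ppmV threshold, exposure-first aggregation, the compensated loss
#' convention at $9.0075/Bu, and the regionally signed default scenario
#' deltas (-1 ppbV Midwest, +3 ppbV Southeast).
#'
#' @param seed integer seed driving all synthetic randomness.
#' @return Nested configuration list.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    mode = "synthetic",
    seed = as.integer(seed),
    output_dir = "o3yield-out",
    scenario_labels = c("BAU", "C19"),
    window = list(start = "2020-05-01", end = "2020-08-01",
                  hours_of_day = NULL),
    threshold_ppmv = 0.04,
    aggregation = "exposure_first",
    dose_response = list(a = 0.0113, convention = "compensated",
                         price_usd_per_bu = 9.0075),
    synthetic = list(
      grid = list(nx = 36L, ny = 24L, cell_size = 12, origin = c(0, 0)),
      counties = list(nx = 9L, ny = 6L, snap = FALSE, jitter_frac = 0.4,
                      n_withheld = 2L),
      field = list(n_days = 92L, baseline_mean = 0.035,
                   diurnal_amplitude = 0.015, spatial_corr_length = 3,
                   noise_sd = 0.004),
      deltas = "default"),
    paths = list(bau_cube = NULL, c19_cube = NULL, counties = NULL),
    log_level = "info")
}

# Recursively reject keys not present in the reference schema.
checkKnownKeys <- function(cfg, ref, path = "") {
  stopifnot(is.list(cfg))
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(cfg[[k]]))
      checkKnownKeys(cfg[[k]], ref[[k]], paste0(path, k, "."))
  }
  invisible(TRUE)
}

#' Validate and complete a pipeline configuration
#'
#' Fills unset keys from [defaultPipelineConfig()], rejects unknown keys,
#' and checks value constraints before any computation runs.
#'
#' @param cfg partial configuration list.
#' @return Completed, validated configuration.
#' @export
validatePipelineConfig <- function(cfg) {
  ref <- defaultPipelineConfig()
  checkKnownKeys(cfg, ref)
  merged <- utils::modifyList(ref, cfg, keep.null = TRUE)
  if (!merged$mode %in% c("synthetic", "files"))
    stop("mode must be 'synthetic' or 'files'")
  if (!merged$aggregation %in% c("exposure_first", "concentration_first"))
    stop("aggregation must be 'exposure_first' or 'concentration_first'")
  if (!is.numeric(merged$threshold_ppmv) || merged$threshold_ppmv <= 0)
    stop("threshold_ppmv must be positive")
  if (length(merged$scenario_labels) != 2L)
    stop("scenario_labels must name exactly two scenarios")
  doseResponseParams(merged$dose_response$a,
                     merged$dose_response$convention,
                     merged$dose_response$price_usd_per_bu)  # validates
  if (merged$mode == "files") {
    p <- merged$paths
    if (is.null(p$bau_cube) || is.null(p$c19_cube) || is.null(p$counties))
      stop("mode 'files' requires paths: bau_cube, c19_cube, counties")
  }
  merged
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  validatePipelineConfig(yaml::read_yaml(path))
}

configWindow <- function(cfg) {
  h <- cfg$window$hours_of_day
  exposureWindow(cfg$window$start, cfg$window$end,
                 if (is.null(h)) 0:23 else h)
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

# Build grid, counties and the two scenario cubes from the synthetic
# section of a config.
synthesizeInputs <- function(cfg) {
  s <- cfg$synthetic
  grid <- makeGrid(s$grid$nx, s$grid$ny, s$grid$cell_size, s$grid$origin)
  deltas <- switch(as.character(s$deltas),
    default = defaultDeltaRegions(grid),
    none = NULL,
    stop("synthetic.deltas must be 'default' or 'none'"))
  fieldCfg <- scenarioFieldConfig(
    seed = cfg$seed, nDays = s$field$n_days,
    baselineMean = s$field$baseline_mean,
    diurnalAmplitude = s$field$diurnal_amplitude,
    spatialCorrLength = s$field$spatial_corr_length,
    noiseSd = s$field$noise_sd, deltaRegions = deltas,
    scenarioLabels = cfg$scenario_labels)
  counties <- makeCounties(grid, s$counties$nx, s$counties$ny,
                           seed = cfg$seed, snap = s$counties$snap,
                           jitterFrac = s$counties$jitter_frac,
                           nWithheld = s$counties$n_withheld)
  cubes <- generateScenarioFields(grid, fieldCfg)
  list(grid = grid, counties = counties, cubes = cubes)
}

#' Write synthetic pipeline inputs to disk
#'
#' Materialises the synthetic scenario cubes (NetCDF) and county set
#' (GeoJSON) described by a configuration, for use with
#' \code{mode: files} runs or the command-line \code{synth} verb.
#'
#' @param cfg configuration list (see [defaultPipelineConfig()]).
#' @param dir output directory (created if needed).
#' @return Named list of the written file paths, invisibly.
#' @export
writeSyntheticInputs <- function(cfg = defaultPipelineConfig(),
                                 dir = cfg$output_dir) {
  cfg <- validatePipelineConfig(cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- withStage("synthetic_data", synthesizeInputs(cfg))
  labels <- cfg$scenario_labels
  paths <- list(
    bau_cube = file.path(dir, paste0("o3_", labels[1L], ".nc")),
    c19_cube = file.path(dir, paste0("o3_", labels[2L], ".nc")),
    counties = file.path(dir, "counties.geojson"))
  writeO3Cube(inputs$cubes[[1L]], paths$bau_cube)
  writeO3Cube(inputs$cubes[[2L]], paths$c19_cube)
  writeCounties(inputs$counties, paths$counties)
  invisible(paths)
}

#' Run the full exposure-to-impact pipeline
#'
#' Executes every stage for both scenarios — input (synthetic generation
#' or file ingestion), per-cell AOT40, area-weighted county aggregation,
#' dose-response impacts, scenario differencing and report assembly —
#' and writes the tabular outputs as CSV: one impact table per scenario,
#' per-county deltas, regional delta ranges, per-scenario totals and the
#' overall summary. Deterministic given the configuration (including its
#' seed); a failure in any stage aborts with the stage named.
#'
#' @param cfg configuration list or path to a YAML file; see
#'   [defaultPipelineConfig()].
#' @param outputDir overrides \code{cfg$output_dir}; \code{NULL} keeps
#'   the configured directory, \code{NA} suppresses all file output.
#' @return The [ScenarioReport-class], invisibly.
#' @export
runPipeline <- function(cfg = defaultPipelineConfig(), outputDir = NULL) {
  if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
  else cfg <- validatePipelineConfig(cfg)
  if (!is.null(outputDir)) cfg$output_dir <- outputDir
  labels <- cfg$scenario_labels

  if (cfg$mode == "synthetic") {
    inputs <- withStage("synthetic_data", synthesizeInputs(cfg))
  } else {
    inputs <- withStage("ingest", {
      cubes <- list(readO3Cube(cfg$paths$bau_cube),
                    readO3Cube(cfg$paths$c19_cube))
      names(cubes) <- labels
      counties <- readCounties(cfg$paths$counties)
      list(grid = gridSpec(cubes[[1L]]), counties = counties, cubes = cubes)
    })
  }

  window <- configWindow(cfg)
  params <- doseResponseParams(cfg$dose_response$a,
                               cfg$dose_response$convention,
                               cfg$dose_response$price_usd_per_bu)
  weights <- withStage("area_weights",
                       computeAreaWeights(inputs$grid, inputs$counties))
  impacts <- lapply(labels, function(lab) {
    exposure <- withStage(paste0("exposure[", lab, "]"),
      countyAOT40(inputs$cubes[[lab]], weights, window,
                  cfg$threshold_ppmv, order = cfg$aggregation))
    withStage(paste0("impact[", lab, "]"),
              countyImpacts(exposure, inputs$counties, params))
  })
  names(impacts) <- labels

  report <- withStage("report",
    buildScenarioReport(impacts[[1L]], impacts[[2L]], labels = labels,
                        price = params$priceUsdPerBu))

  if (!is.na(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(name) file.path(cfg$output_dir, name)
    for (lab in labels)
      write.csv(impacts[[lab]], out(paste0("impacts_", lab, ".csv")),
                row.names = FALSE)
    write.csv(countyDeltas(report), out("county_deltas.csv"),
              row.names = FALSE)
    write.csv(regionalRanges(report), out("regional_summary.csv"),
              row.names = FALSE)
    write.csv(scenarioTotals(report), out("totals.csv"), row.names = FALSE)
    ov <- overallSummary(report)
    write.csv(data.frame(quantity = names(ov),
                         value = unlist(ov, use.names = FALSE)),
              out("overall.csv"), row.names = FALSE)
  }
  invisible(report)
}
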