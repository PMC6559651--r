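#' Run the full HSI analysis pipeline
#'
#' Reads the configured inputs, computes seasonal means and station HSI
#' scores, optionally interpolates them over a coastline and verifies them
#' against a population survey, and writes all result tables plus a run
#' manifest to the output directory.
#'
#' The configuration is a named list (or path to a YAML file) with
#' elements: `env_csv` (required), `out_dir` (required), `curve_config`
#' (optional; bundled defaults used when absent), `respiration_csv`
#' (optional; when present the growth-salinity curve is recalibrated from
#' the trials), `coastline_geojson` (optional), `quadrats_csv` +
#' `individuals_csv` (optional), `weight_mode` (`"normalized"` or
#' `"as_printed"`), `bootstrap_B` (default 1000) and `seed` (required when
#' verification runs, as the bootstrap is stochastic).
#'
#' @param config named list or YAML file path.
#' @return named list of output file paths, invisibly; the run manifest
#'   (`manifest.json`) records package version, seed, weight mode and the
#'   files written.
#' @export
run_hsi_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  for (req in c("env_csv", "out_dir"))
    if (is.null(config[[req]])) stop("pipeline config missing: ", req)
  for (f in c("env_csv", "curve_config", "respiration_csv",
              "coastline_geojson", "quadrats_csv", "individuals_csv"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("input file not found: ", config[[f]])
  weight_mode <- if (is.null(config$weight_mode)) "normalized"
                 else config$weight_mode
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()

  curveset <- if (is.null(config$curve_config)) default_curveset()
              else load_curveset(config$curve_config)
  if (!is.null(config$respiration_csv)) {
    trials <- utils::read.csv(config$respiration_csv)
    curveset$S_G <- calibrate_salinity_curve(trials)
  }

  records <- read_env_survey(config$env_csv)
  sm <- seasonal_means(records)
  p <- file.path(out_dir, "seasonal_means.csv")
  utils::write.csv(sm, p, row.names = FALSE)
  outputs["seasonal_means"] <- p

  hsi <- hsi_from_means(sm, curveset, weight_mode)
  p <- file.path(out_dir, "hsi_scores.csv")
  utils::write.csv(hsi, p, row.names = FALSE)
  outputs["hsi_scores"] <- p

  if (!is.null(config$coastline_geojson)) {
    coast <- read_coastline(config$coastline_geojson)
    seg <- coastline_segments(coast, hsi)
    p <- file.path(out_dir, "coastline_segments.csv")
    utils::write.csv(seg, p, row.names = FALSE)
    outputs["coastline_segments"] <- p
    cls <- coastline_class_lengths(coast, hsi)
    p <- file.path(out_dir, "class_lengths.csv")
    utils::write.csv(cls, p, row.names = FALSE)
    outputs["class_lengths"] <- p
    p <- file.path(out_dir, "coastline_classes.geojson")
    write_class_geojson(seg, coast, p)
    outputs["coastline_classes"] <- p
  }

  if (!is.null(config$quadrats_csv)) {
    if (is.null(config$seed))
      stop("pipeline config missing: seed (required for bootstrap verification)")
    quadrats <- utils::read.csv(config$quadrats_csv)
    individuals <- if (!is.null(config$individuals_csv))
      utils::read.csv(config$individuals_csv) else NULL
    pop <- site_summary(quadrats, individuals)
    p <- file.path(out_dir, "population_summary.csv")
    utils::write.csv(pop, p, row.names = FALSE)
    outputs["population_summary"] <- p
    B <- if (is.null(config$bootstrap_B)) 1000L else config$bootstrap_B
    ver <- verify_hsi(hsi, pop, B = B, seed = config$seed)
    ver$min_hsi_with_oysters <- attr(ver, "min_hsi_with_oysters")
    p <- file.path(out_dir, "verification.csv")
    utils::write.csv(ver, p, row.names = FALSE)
    outputs["verification"] <- p
  }

  manifest <- list(
    package = "oysterHSI",
    version = as.character(utils::packageVersion("oysterHSI")),
    weight_mode = weight_mode,
    seed = config$seed,
    bootstrap_B = config$bootstrap_B,
    n_stations = nrow(sm),
    outputs = as.list(outputs))
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  outputs["manifest"] <- p
  invisible(outputs)
}

#' Validate pipeline input files
#'
#' Schema and range checks that report rather than stop: missing columns
#' are errors in the report, physically implausible values (negative
#' concentrations, DO saturation outside 0--200%, values outside the
#' typical field envelopes) are warnings. GeoJSON coastlines are checked
#' for a supported geometry with at least two vertices.
#'
#' @param env_csv,coastline_geojson,quadrats_csv,individuals_csv optional
#'   paths; only supplied files are checked.
#' @return data.frame with columns `file`, `severity` (`error`/`warning`),
#'   `message`; zero rows when everything is well-formed.
#' @export
validate_inputs <- function(env_csv = NULL, coastline_geojson = NULL,
                            quadrats_csv = NULL, individuals_csv = NULL) {
  issues <- list()
  add <- function(file, severity, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      file = file, severity = severity, message = message,
      stringsAsFactors = FALSE)

  if (!is.null(env_csv)) {
    if (!file.exists(env_csv)) {
      add(env_csv, "error", "file not found")
    } else {
      rec <- utils::read.csv(env_csv, stringsAsFactors = FALSE)
      miss <- setdiff(env_csv_columns(), names(rec))
      for (m in miss) add(env_csv, "error", paste("missing column:", m))
      if (!length(miss)) {
        if (any(is.na(as.Date(rec$date, optional = TRUE))))
          add(env_csv, "error", "unparseable dates")
        rng <- list(salinity_ppt = c(0, 45), do_pct_sat = c(0, 200),
                    ph = c(5, 10), pim_mg_l = c(0, Inf),
                    chla_ug_l = c(0, Inf), velocity_m_s = c(0, Inf),
                    temp_c = c(5, 40))
        for (cn in names(rng)) {
          bad <- sum(rec[[cn]] < rng[[cn]][1L] | rec[[cn]] > rng[[cn]][2L],
                     na.rm = TRUE)
          if (bad) add(env_csv, "warning",
                       sprintf("%d out-of-range values in %s", bad, cn))
        }
      }
    }
  }
  if (!is.null(coastline_geojson)) {
    if (!file.exists(coastline_geojson)) {
      add(coastline_geojson, "error", "file not found")
    } else {
      ok <- tryCatch({read_coastline(coastline_geojson); TRUE},
                     error = function(e) e$message)
      if (!isTRUE(ok)) add(coastline_geojson, "error", ok)
    }
  }
  check_csv <- function(path, req) {
    if (is.null(path)) return()
    if (!file.exists(path)) { add(path, "error", "file not found"); return() }
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    for (m in setdiff(req, names(d)))
      add(path, "error", paste("missing column:", m))
  }
  check_csv(quadrats_csv, c("site_id", "quadrat_id", "area_m2", "live_count"))
  check_csv(individuals_csv,
            c("site_id", "shell_height_cm", "dry_flesh_g", "dry_shell_g"))

  if (!length(issues))
    return(data.frame(file = character(), severity = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}
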