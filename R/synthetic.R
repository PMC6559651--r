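#' Configuration for the synthetic survey generator
#'
#' The generator emulates the structure of a one-year, 80-station
#' monsoon-coast survey: stations ordered south to north along a
#' coastline, 4 monsoon and 3 non-monsoon survey visits, a south-to-north
#' salinity decline, and a monsoon signature (salinity drop, suspended
#' sediment spike, chlorophyll drop, stronger flows). All generated means
#' stay inside the field envelopes observed for such coasts: salinity
#' 0.5--29.5 ppt, PIM 21--1044 mg/L, chlorophyll-a 0.8--9.6 ug/L,
#' temperature 27--28.6 C, pH 7.4--8.5, DO 49--91% saturation, velocity
#' 0.2--2.4 m/s.
#'
#' Environmental fields per variable: `south` and `north` give the
#' non-monsoon mean at the two ends of the gradient; the monsoon mean is
#' `mult * non-monsoon + delta`; `sd` is the per-record noise standard
#' deviation. The population block controls the oyster response to true
#' HSI: zero density below `hsi_threshold`, expected density rising
#' linearly to `density_max` at HSI = 1, negative-binomial quadrat counts
#' with dispersion `nb_size`, and shell height / condition index rising
#' linearly in HSI.
#'
#' @param n_stations number of survey stations.
#' @param n_surveys_monsoon,n_surveys_nonmonsoon visits per season.
#' @param year survey calendar year (drives record dates).
#' @param ... replacements for individual defaults (supplied elements are
#'   merged over the default lists, e.g. `population = list(nb_size = 2)`).
#' @return a list of class `hsi_generator_config`.
#' @export
generator_config <- function(n_stations = 80, n_surveys_monsoon = 4,
                             n_surveys_nonmonsoon = 3, year = 2016, ...) {
  cfg <- list(
    n_stations = n_stations,
    n_surveys_monsoon = n_surveys_monsoon,
    n_surveys_nonmonsoon = n_surveys_nonmonsoon,
    year = year,
    env = list(
      # south/north: non-monsoon means at gradient ends; monsoon = mult*nm + delta
      temperature = list(south = 27.9, north = 27.7, mult = 1, delta = 0.4,  sd = 0.2),
      salinity    = list(south = 29,   north = 3,    mult = 1, delta = -9,   sd = 1.5),
      do_sat      = list(south = 88,   north = 56,   mult = 1, delta = 0,    sd = 3),
      ph          = list(south = 8.35, north = 7.55, mult = 1, delta = -0.25, sd = 0.05),
      chla        = list(south = 8.5,  north = 2,    mult = 0.55, delta = 0, sd = 0.4),
      pim         = list(south = 90,   north = 510,  mult = 2.1, delta = 0,  sd = 30),
      velocity    = list(south = 0.3,  north = 0.7,  mult = 1, delta = 0.55, sd = 0.08)),
    envelopes = list(
      temperature = c(27, 28.6), salinity = c(0.5, 29.5), do_sat = c(49, 91),
      ph = c(7.4, 8.5), chla = c(0.8, 9.6), pim = c(21, 1044),
      velocity = c(0.2, 2.4)),
    coast = list(lon_south = 92.30, lat_south = 20.75,
                 lon_north = 91.45, lat_north = 22.90,
                 wiggle_deg = 0.08, n_vertices = 200),
    population = list(
      quadrat_area_m2 = 0.0625, n_quadrats = 6, n_measure = 12,
      hsi_threshold = 0.27, density_max = 1540, nb_size = 5,
      height_base = 2.5, height_slope = 5, height_sd = 0.8,
      cindex_base = 3.8, cindex_slope = 7.4, cindex_sd = 0.6),
    respiration = list(
      salinities = seq(0, 35, by = 5),
      true_si = c(0, 0.1, 0.4, 0.6, 0.8, 1, 1, 0.9),
      n_reps = 12, rmax = 0.5, noise_sd = 0.06,
      volume_l = 1, po2_start = 6, duration_h = 2))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "hsi_generator_config")
}

# stations on the synthetic coastline; u = 0 south ... 1 north
gen_stations <- function(config) {
  n <- config$n_stations
  u <- if (n == 1L) 0 else (seq_len(n) - 1) / (n - 1)
  co <- config$coast
  data.frame(
    station_id = sprintf("S%03d", seq_len(n)),
    u = u,
    lon = co$lon_south + u * (co$lon_north - co$lon_south) +
      co$wiggle_deg * sin(6 * pi * u),
    lat = co$lat_south + u * (co$lat_north - co$lat_south),
    stringsAsFactors = FALSE)
}

# noise-free seasonal mean of one variable at gradient position u
true_seasonal_mean <- function(config, variable, u, season) {
  p <- config$env[[variable]]
  nm <- p$south + u * (p$north - p$south)
  val <- if (season == "monsoon") p$mult * nm + p$delta else nm
  env <- config$envelopes[[variable]]
  pmin(pmax(val, env[1L]), env[2L])
}

#' True (noise-free) station states of the synthetic survey
#'
#' The generator's ground truth: the seasonal means each station's records
#' are drawn around, in the same wide layout as [seasonal_means()], plus
#' the true HSI obtained by pushing those noise-free means through the
#' model with the given curves.
#'
#' @param config a [generator_config()].
#' @param curveset curves used to define the true HSI.
#' @param weight_mode see [ci_post_settlement()].
#' @return data.frame: station coordinates, per-variable `_m`/`_nm`/
#'   `_annual` true means, and `true_hsi`.
#' @export
generator_truth <- function(config = generator_config(),
                            curveset = default_curveset(),
                            weight_mode = "normalized") {
  st <- gen_stations(config)
  sm <- st[, c("station_id", "lon", "lat")]
  for (v in names(config$env)) {
    mu_m <- true_seasonal_mean(config, v, st$u, "monsoon")
    mu_nm <- true_seasonal_mean(config, v, st$u, "non_monsoon")
    sm[[paste0(v, "_m")]] <- mu_m
    sm[[paste0(v, "_m_sd")]] <- 0
    sm[[paste0(v, "_nm")]] <- mu_nm
    sm[[paste0(v, "_nm_sd")]] <- 0
    sm[[paste0(v, "_annual")]] <- annual_mean(mu_m, mu_nm)
  }
  res <- hsi_from_means(sm, curveset, weight_mode)
  sm$true_hsi <- res$hsi
  sm
}

survey_dates <- function(config) {
  y <- config$year
  monsoon <- as.Date(sprintf("%d-%02d-15", y, 6:9))[seq_len(config$n_surveys_monsoon)]
  nonmonsoon <- as.Date(sprintf("%d-%02d-15", y, c(1, 5, 11)))[seq_len(config$n_surveys_nonmonsoon)]
  list(monsoon = monsoon, non_monsoon = nonmonsoon)
}

#' Generate a synthetic environmental survey
#'
#' One record per station and survey visit: the station's true seasonal
#' mean plus Gaussian noise, truncated to the configured physical
#' envelopes. Survey dates fall inside the correct calendar seasons so the
#' records exercise [assign_season()]. Deterministic for a fixed seed.
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return data.frame in the survey CSV layout ([read_env_survey()]).
#' @export
gen_env_survey <- function(config = generator_config(), seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  st <- gen_stations(config)
  dates <- survey_dates(config)
  all_dates <- c(dates$monsoon, dates$non_monsoon)
  seasons <- rep(c("monsoon", "non_monsoon"),
                 c(length(dates$monsoon), length(dates$non_monsoon)))
  grid <- expand.grid(i = seq_len(nrow(st)), d = seq_along(all_dates))
  rec <- data.frame(
    station_id = st$station_id[grid$i],
    lon = st$lon[grid$i], lat = st$lat[grid$i],
    date = all_dates[grid$d],
    stringsAsFactors = FALSE)
  cols <- env_variables()
  for (v in names(cols)) {
    mu <- ifelse(seasons[grid$d] == "monsoon",
                 true_seasonal_mean(config, v, st$u[grid$i], "monsoon"),
                 true_seasonal_mean(config, v, st$u[grid$i], "non_monsoon"))
    x <- mu + stats::rnorm(nrow(rec), 0, config$env[[v]]$sd)
    env <- config$envelopes[[v]]
    rec[[cols[[v]]]] <- pmin(pmax(x, env[1L]), env[2L])
  }
  rec[order(rec$station_id, rec$date), , drop = FALSE]
}

#' Synthetic coastline polyline
#'
#' A gently wiggling polyline through the station gradient, densified to
#' `n_vertices` vertices.
#'
#' @param config a [generator_config()].
#' @return a [coastline()] object.
#' @export
gen_coastline <- function(config = generator_config()) {
  co <- config$coast
  u <- seq(0, 1, length.out = co$n_vertices)
  coastline(
    lon = co$lon_south + u * (co$lon_north - co$lon_south) +
      co$wiggle_deg * sin(6 * pi * u),
    lat = co$lat_south + u * (co$lat_north - co$lat_south))
}

#' Expected oyster density at a true HSI score
#'
#' The generator's density response: zero below the occupancy threshold,
#' then rising linearly to `density_max` at HSI = 1.
#'
#' @param hsi numeric vector of true HSI scores.
#' @param config a [generator_config()].
#' @return expected density in individuals per m2.
#' @export
expected_density <- function(hsi, config = generator_config()) {
  p <- config$population
  ifelse(hsi < p$hsi_threshold, 0,
         p$density_max * (hsi - p$hsi_threshold) / (1 - p$hsi_threshold))
}

#' Generate a synthetic oyster population survey
#'
#' For each station, quadrat counts are negative-binomial around the
#' expected density (overdispersion set by `nb_size`); stations below the
#' HSI occupancy threshold get all-zero counts and no measured
#' individuals. Measured individuals get shell heights and condition
#' indices rising linearly in true HSI with Gaussian noise (condition
#' index confined to roughly 4--11%); dry shell weight scales with the
#' cube of height and dry flesh weight follows from the condition index.
#'
#' @param stations data.frame with columns `station_id` and `true_hsi`
#'   (e.g. from [generator_truth()]).
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return list with `quadrats` (site_id, quadrat_id, area_m2, live_count)
#'   and `individuals` (site_id, quadrat_id, shell_height_cm, dry_flesh_g,
#'   dry_shell_g).
#' @export
gen_population <- function(stations, config = generator_config(), seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(all(c("station_id", "true_hsi") %in% names(stations)))
  set.seed(seed)
  p <- config$population
  quadrats <- list(); individuals <- list()
  for (i in seq_len(nrow(stations))) {
    hsi <- stations$true_hsi[i]
    sid <- stations$station_id[i]
    mu <- expected_density(hsi, config) * p$quadrat_area_m2
    counts <- if (mu == 0) rep(0L, p$n_quadrats)
              else stats::rnbinom(p$n_quadrats, mu = mu, size = p$nb_size)
    quadrats[[i]] <- data.frame(
      site_id = sid, quadrat_id = seq_len(p$n_quadrats),
      area_m2 = p$quadrat_area_m2, live_count = counts,
      stringsAsFactors = FALSE)
    n_ind <- min(p$n_measure, sum(counts))
    if (n_ind > 0L) {
      h <- pmax(stats::rnorm(n_ind, p$height_base + p$height_slope * hsi,
                             p$height_sd), 0.5)
      ci <- pmin(pmax(stats::rnorm(n_ind, p$cindex_base + p$cindex_slope * hsi,
                                   p$cindex_sd), 3.5), 11.5)
      shell <- 0.08 * h^3
      individuals[[length(individuals) + 1L]] <- data.frame(
        site_id = sid,
        quadrat_id = rep_len(which(counts > 0), n_ind),
        shell_height_cm = h,
        dry_flesh_g = ci / 100 * shell,
        dry_shell_g = shell,
        stringsAsFactors = FALSE)
    }
  }
  list(quadrats = do.call(rbind, quadrats),
       individuals = if (length(individuals)) do.call(rbind, individuals)
                     else data.frame(site_id = character(), quadrat_id = integer(),
                                     shell_height_cm = numeric(),
                                     dry_flesh_g = numeric(),
                                     dry_shell_g = numeric()))
}

#' Generate synthetic closed-chamber respiration trials
#'
#' Eight salinity levels with `n_reps` replicate trials each; true rates
#' follow the configured unimodal salinity response (`rmax * true_si`)
#' plus Gaussian noise (truncated at zero consumption), converted to
#' start/end oxygen concentrations of a fixed-volume chamber.
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @param noise_sd noise standard deviation as a fraction of `rmax`;
#'   defaults to the configured value; 0 gives exact true rates.
#' @return data.frame in the respiration CSV layout understood by
#'   [calibrate_salinity_curve()].
#' @export
gen_respiration <- function(config = generator_config(), seed,
                            noise_sd = config$respiration$noise_sd) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  rp <- config$respiration
  stopifnot(length(rp$true_si) == length(rp$salinities))
  lev <- rep(rp$salinities, each = rp$n_reps)
  true_rate <- rep(rp$rmax * rp$true_si, each = rp$n_reps)
  rate <- pmax(true_rate + stats::rnorm(length(lev), 0, noise_sd * rp$rmax), 0)
  data.frame(
    salinity_ppt = lev,
    volume_l = rp$volume_l,
    po2_start_ml_l = rp$po2_start,
    po2_end_ml_l = rp$po2_start - rate * rp$duration_h / rp$volume_l,
    duration_h = rp$duration_h)
}

#' Generate site-level verification data with target correlations
#'
#' Site-mean population descriptors constructed so that their Pearson
#' correlation with the true HSI equals the requested targets in
#' expectation: each descriptor is a linear transform of HSI plus
#' Gaussian noise whose variance is set from the target correlation.
#' Used to test that the verification statistics recover known
#' relationships; values are statistical abstractions of site means, not
#' physically bounded quantities.
#'
#' @param n number of sites.
#' @param targets named vector of target correlations for `density`,
#'   `shell_height`, `condition_index`.
#' @param seed integer seed.
#' @return data.frame with `site_id`, `true_hsi`, `density_mean`,
#'   `height_mean`, `cindex_mean`.
#' @export
gen_verification_sites <- function(n = 53,
                                   targets = c(density = 0.87,
                                               shell_height = 0.95,
                                               condition_index = 0.98),
                                   seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  hsi <- stats::runif(n, 0.05, 0.95)
  s_h <- stats::sd(hsi)
  noisy <- function(a, b, r) {
    a + b * hsi + stats::rnorm(n, 0, abs(b) * s_h * sqrt(1 / r^2 - 1))
  }
  data.frame(
    site_id = sprintf("S%03d", seq_len(n)),
    true_hsi = hsi,
    density_mean = noisy(-100, 1500, targets[["density"]]),
    height_mean = noisy(2.5, 5, targets[["shell_height"]]),
    cindex_mean = noisy(3.8, 7.4, targets[["condition_index"]]),
    stringsAsFactors = FALSE)
}

#' Write a complete synthetic demo dataset to disk
#'
#' Emits the CSV/GeoJSON files the pipeline reads: environmental survey,
#' coastline, respiration trials, and the population survey (quadrats and
#' individuals), all derived from one seed.
#'
#' @param dir output directory (created if needed).
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return named character vector of the file paths written.
#' @export
make_fixtures <- function(dir, config = generator_config(), seed) {
  if (missing(seed)) stop("a seed is required")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(env_survey = file.path(dir, "env_survey.csv"),
             coastline = file.path(dir, "coastline.geojson"),
             respiration = file.path(dir, "respiration_trials.csv"),
             quadrats = file.path(dir, "quadrats.csv"),
             individuals = file.path(dir, "individuals.csv"))
  rec <- gen_env_survey(config, seed = seed)
  utils::write.csv(rec, paths[["env_survey"]], row.names = FALSE)
  write_coastline(gen_coastline(config), paths[["coastline"]])
  utils::write.csv(gen_respiration(config, seed = seed + 1L),
                   paths[["respiration"]], row.names = FALSE)
  truth <- generator_truth(config)
  pop <- gen_population(truth, config, seed = seed + 2L)
  utils::write.csv(pop$quadrats, paths[["quadrats"]], row.names = FALSE)
  utils::write.csv(pop$individuals, paths[["individuals"]], row.names = FALSE)
  paths
}
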