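#' Environmental survey ingestion and seasonal aggregation
#'
#' Station survey records carry the seven model variables. The survey CSV
#' dialect has columns `station_id, lon, lat, date, temp_c, salinity_ppt,
#' do_pct_sat, ph, chla_ug_l, pim_mg_l, velocity_m_s` with ISO-8601 dates.
#'
#' @param path CSV file path.
#' @param check validate physical ranges (non-negative salinity/PIM/chla/
#'   velocity, DO saturation within 0--200%).
#' @return data.frame of environmental records with a `Date` date column.
#' @export
read_env_survey <- function(path, check = TRUE) {
  if (!file.exists(path)) stop("environmental survey file not found: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(env_csv_columns(), names(rec))
  if (length(miss))
    stop("survey CSV missing columns: ", paste(miss, collapse = ", "))
  rec$date <- as.Date(rec$date)
  if (check) validate_env_records(rec)
  rec
}

env_csv_columns <- function() {
  c("station_id", "lon", "lat", "date", "temp_c", "salinity_ppt",
    "do_pct_sat", "ph", "chla_ug_l", "pim_mg_l", "velocity_m_s")
}

# variable key used internally -> survey CSV column
env_variables <- function() {
  c(temperature = "temp_c", salinity = "salinity_ppt", do_sat = "do_pct_sat",
    ph = "ph", chla = "chla_ug_l", pim = "pim_mg_l", velocity = "velocity_m_s")
}

validate_env_records <- function(rec) {
  if (any(is.na(rec$date))) stop("unparseable dates in survey records")
  if (any(rec$salinity_ppt < 0, na.rm = TRUE)) stop("negative salinity")
  if (any(rec$do_pct_sat < 0 | rec$do_pct_sat > 200, na.rm = TRUE))
    stop("dissolved-oxygen saturation outside [0, 200] %")
  if (any(rec$pim_mg_l < 0, na.rm = TRUE)) stop("negative PIM")
  if (any(rec$chla_ug_l < 0, na.rm = TRUE)) stop("negative chlorophyll-a")
  if (any(rec$velocity_m_s < 0, na.rm = TRUE)) stop("negative flow velocity")
  invisible(rec)
}

#' Assign the monsoon / non-monsoon season of a date
#'
#' June--September is the monsoon; October--May (covering post-monsoon,
#' winter and pre-monsoon) is the non-monsoon period.
#'
#' @param date a `Date` vector (or anything `as.Date()` accepts).
#' @return character vector, `"monsoon"` or `"non_monsoon"`.
#' @examples
#' assign_season(as.Date(c("2016-07-15", "2016-01-10")))
#' @export
assign_season <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  ifelse(m >= 6L & m <= 9L, "monsoon", "non_monsoon")
}

#' Seasonal means of the environmental variables per station
#'
#' Flood/ebb duplicate measurements (several records for one station on one
#' date) are first averaged to a single record per station-date. Records
#' are then split into monsoon and non-monsoon sets and the arithmetic mean
#' and sample standard deviation of each of the seven variables are
#' computed per station and season, together with the month-weighted annual
#' mean (see [annual_mean()]).
#'
#' A station observed in only one season keeps `NA` for the missing
#' season's columns; a season with a single record has `NA` standard
#' deviation.
#'
#' @param records data.frame of environmental records as returned by
#'   [read_env_survey()].
#' @return data.frame with one row per station: `station_id`, `lon`, `lat`,
#'   then for each variable `<var>_m`, `<var>_m_sd`, `<var>_nm`,
#'   `<var>_nm_sd`, `<var>_annual`, plus record counts `n_monsoon` and
#'   `n_nonmonsoon`.
#' @export
seasonal_means <- function(records) {
  if (nrow(records) == 0L) stop("no survey records supplied")
  rec <- collapse_tidal_duplicates(records)
  rec$season <- assign_season(rec$date)
  vars <- env_variables()
  stations <- unique(rec$station_id)
  rows <- lapply(stations, function(st) {
    sub <- rec[rec$station_id == st, , drop = FALSE]
    out <- list(station_id = st, lon = sub$lon[1L], lat = sub$lat[1L])
    m <- sub[sub$season == "monsoon", , drop = FALSE]
    nm <- sub[sub$season == "non_monsoon", , drop = FALSE]
    for (v in names(vars)) {
      col <- vars[[v]]
      mu_m <- if (nrow(m)) mean(m[[col]]) else NA_real_
      mu_nm <- if (nrow(nm)) mean(nm[[col]]) else NA_real_
      out[[paste0(v, "_m")]] <- mu_m
      out[[paste0(v, "_m_sd")]] <- if (nrow(m) > 1L) stats::sd(m[[col]]) else NA_real_
      out[[paste0(v, "_nm")]] <- mu_nm
      out[[paste0(v, "_nm_sd")]] <- if (nrow(nm) > 1L) stats::sd(nm[[col]]) else NA_real_
      out[[paste0(v, "_annual")]] <-
        if (is.na(mu_m) || is.na(mu_nm)) NA_real_ else annual_mean(mu_m, mu_nm)
    }
    out$n_monsoon <- nrow(m)
    out$n_nonmonsoon <- nrow(nm)
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# average flood/ebb (or other within-visit) duplicates to one record
# per station-date; keeps first lon/lat
collapse_tidal_duplicates <- function(records) {
  key <- interaction(records$station_id, records$date, drop = TRUE)
  if (!anyDuplicated(key)) return(records)
  vars <- unname(env_variables())
  pieces <- lapply(split(records, key), function(g) {
    out <- g[1L, , drop = FALSE]
    out[vars] <- lapply(g[vars], mean)
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Month-weighted annual mean of seasonal means
#'
#' The monsoon covers 4 of 12 months and the non-monsoon 8 of 12, so the
#' annual mean is the seasonal means weighted 4/12 and 8/12 — not weighted
#' by survey counts, which would over-represent the monsoon (4 monsoon vs 3
#' non-monsoon surveys).
#'
#' @param mean_m,mean_nm monsoon and non-monsoon seasonal means.
#' @param weights length-2 non-negative weights (monsoon, non-monsoon);
#'   normalised to sum to 1.
#' @return weighted annual mean (vectorised over the means).
#' @examples
#' annual_mean(16.2, 28)   # salinity, ppt
#' @export
annual_mean <- function(mean_m, mean_nm, weights = c(4, 8) / 12) {
  if (length(weights) != 2L || any(!is.finite(weights)))
    stop("weights must be two finite numbers")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) <= 0) stop("weights must not both be zero")
  weights <- weights / sum(weights)
  weights[1L] * mean_m + weights[2L] * mean_nm
}

#' Two-sample test of a seasonal difference in one variable
#'
#' Compares monsoon against non-monsoon records of one environmental
#' variable with a two-sided two-sample t-test (Welch by default; set
#' `var_equal = TRUE` for the pooled-variance variant). When both groups
#' are exactly constant with equal means the difference is degenerate and
#' `p = 1` is returned by convention.
#'
#' @param records environmental records data.frame.
#' @param variable one of `temperature`, `salinity`, `do_sat`, `ph`,
#'   `chla`, `pim`, `velocity`.
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return list with `t`, `df`, `p`, and per-season `n`.
#' @export
seasonal_ttest <- function(records, variable, var_equal = FALSE) {
  vars <- env_variables()
  variable <- match.arg(variable, names(vars))
  col <- vars[[variable]]
  season <- assign_season(records$date)
  x <- records[[col]][season == "monsoon"]
  y <- records[[col]][season == "non_monsoon"]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 records per season for a t-test")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = NA_real_, p = 1,
                  n_monsoon = length(x), n_nonmonsoon = length(y)))
    return(list(t = Inf * sign(mean(x) - mean(y)), df = NA_real_, p = 0,
                n_monsoon = length(x), n_nonmonsoon = length(y)))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n_monsoon = length(x), n_nonmonsoon = length(y))
}
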