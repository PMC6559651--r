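#' Suitability-index vector for one station and season
#'
#' Evaluates all eight curves at the station's seasonal means. The salinity
#' mean feeds both the settlement curve (`Ss`) and the growth curve
#' (`S_G`); the remaining variables map one-to-one.
#'
#' @param means named numeric vector (or one-row data.frame slice) with
#'   elements `temperature`, `salinity`, `do_sat`, `ph`, `chla`, `pim`,
#'   `velocity`.
#' @param curveset an `hsi_curveset` from [load_curveset()] or
#'   [default_curveset()].
#' @param station label used in error messages.
#' @return named numeric vector `si_Ss`, `si_V`, `si_T`, `si_Sg`, `si_pH`,
#'   `si_DO`, `si_PIM`, `si_Chla`, each in \[0, 1\].
#' @export
si_vector <- function(means, curveset, station = "?") {
  stopifnot(inherits(curveset, "hsi_curveset"))
  means <- unlist(means)
  need <- c(Ss = "salinity", V = "velocity", T = "temperature",
            S_G = "salinity", pH = "ph", DO = "do_sat",
            PIM = "pim", Chla = "chla")
  vals <- vapply(names(need), function(id) {
    v <- means[[need[[id]]]]
    if (is.null(v) || is.na(v))
      stop(sprintf("station %s: missing seasonal mean for %s",
                   station, need[[id]]))
    eval_suitability(curveset[[id]], v)
  }, numeric(1))
  names(vals) <- c("si_Ss", "si_V", "si_T", "si_Sg",
                   "si_pH", "si_DO", "si_PIM", "si_Chla")
  vals
}

#' Settlement-stage component index
#'
#' Within each season the settlement component index is the geometric mean
#' of the settlement-salinity and flow-velocity SIs:
#' `CI_settlement-season = sqrt(SI_Ss * SI_V)`. The two seasons are then
#' combined by their arithmetic mean with equal weights: larval settlement
#' can succeed in either season, so an unsuitable monsoon does not zero the
#' stage.
#'
#' @param si_m,si_nm SI vectors for the monsoon and non-monsoon seasons
#'   (from [si_vector()]).
#' @return list with `ci_m`, `ci_nm` and the combined `ci`.
#' @export
ci_settlement <- function(si_m, si_nm) {
  ci_m <- sqrt(si_m[["si_Ss"]] * si_m[["si_V"]])
  ci_nm <- sqrt(si_nm[["si_Ss"]] * si_nm[["si_V"]])
  list(ci_m = ci_m, ci_nm = ci_nm, ci = (ci_m + ci_nm) / 2)
}

#' Post-settlement-stage component index
#'
#' Within each season the post-settlement component index is the geometric
#' mean of the six growth-stage SIs (temperature, growth salinity, pH,
#' dissolved oxygen, PIM, chlorophyll-a), i.e. the 1/6 power of their
#' product — so a zero SI for any variable zeroes the seasonal CI. Seasons
#' are combined multiplicatively because growth conditions must be
#' adequate year-round:
#'
#' * `weight_mode = "normalized"` (default): exponents 4/12 and 8/12,
#'   the season lengths as fractions of the year, so the combination is a
#'   true weighted geometric mean bounded by the two seasonal CIs.
#' * `weight_mode = "as_printed"`: exponents 1/3 and 1/3, reproducing the
#'   form in which the combination rule is commonly written; with both
#'   exponents 1/3 the result can exceed either seasonal CI (e.g. equal
#'   seasonal CIs c give c^(2/3) >= c).
#'
#' @inheritParams ci_settlement
#' @param weight_mode `"normalized"` or `"as_printed"`.
#' @return list with `ci_m`, `ci_nm` and the combined `ci`.
#' @export
ci_post_settlement <- function(si_m, si_nm,
                               weight_mode = c("normalized", "as_printed")) {
  weight_mode <- match.arg(weight_mode)
  six <- c("si_T", "si_Sg", "si_pH", "si_DO", "si_PIM", "si_Chla")
  ci_m <- prod(si_m[six])^(1 / 6)
  ci_nm <- prod(si_nm[six])^(1 / 6)
  exps <- switch(weight_mode,
                 normalized = c(4, 8) / 12,
                 as_printed = c(1, 1) / 3)
  list(ci_m = ci_m, ci_nm = ci_nm,
       ci = ci_m^exps[1L] * ci_nm^exps[2L])
}

#' Combine component indices into the habitat suitability index
#'
#' The minimum-limiting combination rule: if the post-settlement component
#' index is the lowest, it is the HSI (growth conditions cap the habitat);
#' otherwise the HSI is the geometric mean of the two component indices.
#' At equality both branches coincide.
#'
#' @param ci_settlement,ci_post component indices in \[0, 1\].
#' @return HSI in \[0, 1\] (vectorised).
#' @examples
#' combine_hsi(0.6, 0.4)    # post-limited: 0.4
#' combine_hsi(0.49, 0.81)  # sqrt(0.49 * 0.81) = 0.63
#' @export
combine_hsi <- function(ci_settlement, ci_post) {
  ifelse(ci_post < ci_settlement, ci_post, sqrt(ci_post * ci_settlement))
}

#' Suitability category of an HSI score
#'
#' `suitable` for year-round settlement and growth when HSI > 0.50,
#' `less_suitable` for 0.3 < HSI <= 0.5, `least_suitable` for HSI <= 0.3.
#'
#' @param hsi numeric vector in \[0, 1\].
#' @return character vector of categories.
#' @export
hsi_category <- function(hsi) {
  if (any(hsi < 0 | hsi > 1, na.rm = TRUE)) stop("hsi must lie in [0, 1]")
  ifelse(hsi > 0.5, "suitable",
         ifelse(hsi > 0.3, "less_suitable", "least_suitable"))
}

#' Run the full station-level HSI model
#'
#' Composes the pipeline: seasonal aggregation of the survey records,
#' SI evaluation for both seasons, life-stage component indices, the
#' combined HSI, and its class label and suitability category. The
#' computation is deterministic.
#'
#' @param records environmental records ([read_env_survey()]).
#' @param curveset an `hsi_curveset`; defaults to the bundled curves.
#' @param weight_mode cross-season exponents for the post-settlement CI,
#'   see [ci_post_settlement()].
#' @return data.frame with one row per station: coordinates, the six
#'   component-index columns, `hsi`, `class_label`, `category`.
#' @export
hsi_pipeline <- function(records, curveset = default_curveset(),
                         weight_mode = c("normalized", "as_printed")) {
  weight_mode <- match.arg(weight_mode)
  sm <- seasonal_means(records)
  hsi_from_means(sm, curveset, weight_mode)
}

#' HSI scores from precomputed seasonal means
#'
#' Same computation as [hsi_pipeline()] starting from a seasonal-means
#' table ([seasonal_means()]).
#'
#' @param sm seasonal-means data.frame.
#' @inheritParams hsi_pipeline
#' @return see [hsi_pipeline()].
#' @export
hsi_from_means <- function(sm, curveset = default_curveset(),
                           weight_mode = c("normalized", "as_printed")) {
  weight_mode <- match.arg(weight_mode)
  vars <- names(env_variables())
  rows <- lapply(seq_len(nrow(sm)), function(i) {
    st <- sm$station_id[i]
    mu_m <- stats::setNames(as.numeric(sm[i, paste0(vars, "_m")]), vars)
    mu_nm <- stats::setNames(as.numeric(sm[i, paste0(vars, "_nm")]), vars)
    si_m <- si_vector(mu_m, curveset, station = st)
    si_nm <- si_vector(mu_nm, curveset, station = st)
    set <- ci_settlement(si_m, si_nm)
    post <- ci_post_settlement(si_m, si_nm, weight_mode)
    hsi <- combine_hsi(set$ci, post$ci)
    data.frame(station_id = st, lon = sm$lon[i], lat = sm$lat[i],
               ci_settlement_m = set$ci_m, ci_settlement_nm = set$ci_nm,
               ci_settlement = set$ci,
               ci_post_m = post$ci_m, ci_post_nm = post$ci_nm,
               ci_post = post$ci,
               hsi = hsi,
               class_label = classify_hsi(hsi),
               category = hsi_category(hsi),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
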