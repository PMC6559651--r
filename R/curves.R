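#' Suitability-index curves
#'
#' A suitability curve maps one environmental variable to a dimensionless
#' suitability index (SI) in \[0, 1\] by piecewise-linear interpolation
#' between breakpoints. The model uses eight curves: settlement salinity
#' (`Ss`) and flow velocity (`V`) for the larval settlement stage, and
#' temperature (`T`), growth salinity (`S_G`), `pH`, dissolved oxygen
#' (`DO`), particulate inorganic matter (`PIM`) and chlorophyll-a (`Chla`)
#' for the post-settlement stage.
#'
#' @param variable_id one of `"Ss"`, `"V"`, `"T"`, `"S_G"`, `"pH"`, `"DO"`,
#'   `"PIM"`, `"Chla"`.
#' @param x numeric vector of breakpoint positions, strictly increasing, in
#'   the variable's own units (ppt, m/s, degrees C, % saturation, mg/L,
#'   ug/L).
#' @param si numeric vector of suitability values at the breakpoints, each
#'   in \[0, 1\].
#' @param out_of_range one of `"clamp_to_edge"` (default; the curve
#'   plateaus at its edge values outside the breakpoint span) or `"zero"`.
#' @return An object of class `suitability_curve`.
#' @examples
#' cv <- suitability_curve("S_G", x = c(0, 10, 35), si = c(0, 1, 1))
#' eval_suitability(cv, c(0, 5, 10, 40))
#' @seealso [eval_suitability()], [load_curveset()], [default_curveset()]
#' @export
suitability_curve <- function(variable_id, x, si,
                              out_of_range = c("clamp_to_edge", "zero")) {
  variable_id <- match.arg(variable_id, hsi_variable_ids())
  out_of_range <- match.arg(out_of_range)
  x <- as.numeric(x)
  si <- as.numeric(si)
  if (length(x) != length(si))
    stop("breakpoint 'x' and 'si' must have equal length")
  if (length(x) < 2L)
    stop("a suitability curve needs at least 2 breakpoints")
  if (any(!is.finite(x)) || any(!is.finite(si)))
    stop("breakpoints must be finite")
  if (any(diff(x) <= 0))
    stop("breakpoint x values must be strictly increasing")
  if (any(si < 0 | si > 1))
    stop("suitability values must lie in [0, 1]")
  structure(
    list(variable_id = variable_id,
         breakpoints = data.frame(x = x, si = si),
         out_of_range = out_of_range),
    class = "suitability_curve")
}

#' The eight model variable identifiers
#'
#' @return Character vector of the curve identifiers in model order.
#' @export
hsi_variable_ids <- function() {
  c("Ss", "V", "T", "S_G", "pH", "DO", "PIM", "Chla")
}

#' @export
print.suitability_curve <- function(x, ...) {
  cat("Suitability curve for", x$variable_id,
      sprintf("(%d breakpoints, out-of-range: %s)\n",
              nrow(x$breakpoints), x$out_of_range))
  print(x$breakpoints, row.names = FALSE)
  invisible(x)
}

#' Evaluate a suitability curve
#'
#' Linear interpolation between breakpoints; exactly at a breakpoint the
#' stored SI is returned. Outside the breakpoint span the curve's
#' out-of-range policy applies: `clamp_to_edge` holds the edge SI,
#' `zero` returns 0.
#'
#' @param curve a [suitability_curve()].
#' @param x numeric vector of environmental values (curve units).
#' @return numeric vector of SI values in \[0, 1\].
#' @export
eval_suitability <- function(curve, x) {
  stopifnot(inherits(curve, "suitability_curve"))
  if (any(!is.finite(x)))
    stop("cannot evaluate suitability at non-finite values")
  bp <- curve$breakpoints
  out <- stats::approx(bp$x, bp$si, xout = x, rule = 2)$y
  if (curve$out_of_range == "zero")
    out[x < bp$x[1L] | x > bp$x[nrow(bp)]] <- 0
  out
}

#' Respiration rate from a closed-chamber trial
#'
#' Oxygen consumption of a single oyster held in a sealed chamber:
#' `RR = -V * (pO2_end - pO2_start) / t`, in mL O2 per hour, where `V` is
#' chamber volume (L), `pO2` the oxygen concentration (mL/L) at the start
#' and end, and `t` the elapsed time (h). A positive rate means oxygen was
#' consumed.
#'
#' Trials should not let oxygen fall below about 3 mg O2/L (2.1 mL/L at
#' 1 mg = 0.7 mL O2); an ending concentration below that guard level
#' triggers a warning because respiration becomes oxygen-limited.
#'
#' @param chamber_volume chamber volume in litres.
#' @param po2_start,po2_end oxygen concentration (mL O2 per L) at start and
#'   end of the trial.
#' @param duration trial duration in hours.
#' @return respiration rate in mL O2 per hour (vectorised).
#' @export
respiration_rate <- function(chamber_volume, po2_start, po2_end, duration) {
  if (any(chamber_volume <= 0)) stop("chamber_volume must be > 0")
  if (any(duration <= 0)) stop("duration must be > 0")
  if (any(po2_end < O2_GUARD_ML_L))
    warning(sprintf(
      "end-of-trial oxygen below %.1f mL/L (3 mg O2/L): rate may be oxygen-limited",
      O2_GUARD_ML_L))
  -chamber_volume * (po2_end - po2_start) / duration
}

# 3 mg O2/L expressed in mL O2/L (1 mg O2 = 0.7 mL O2 at STP)
O2_GUARD_ML_L <- 2.1

#' Calibrate the growth-salinity suitability curve from respiration trials
#'
#' Respiration rates are computed per trial, averaged within each tested
#' salinity level, and standardised so that the maximum mean rate maps to
#' SI = 1. Breakpoints are placed at the tested salinities. Replicates are
#' averaged before normalisation.
#'
#' @param trials data.frame with columns `salinity_ppt`, `volume_l`,
#'   `po2_start_ml_l`, `po2_end_ml_l`, `duration_h`.
#' @param out_of_range out-of-range policy for the resulting curve.
#' @return a [suitability_curve()] for `S_G` with `max(si) == 1`.
#' @export
calibrate_salinity_curve <- function(trials, out_of_range = "clamp_to_edge") {
  req <- c("salinity_ppt", "volume_l", "po2_start_ml_l", "po2_end_ml_l",
           "duration_h")
  miss <- setdiff(req, names(trials))
  if (length(miss))
    stop("trials missing columns: ", paste(miss, collapse = ", "))
  rr <- respiration_rate(trials$volume_l, trials$po2_start_ml_l,
                         trials$po2_end_ml_l, trials$duration_h)
  lev <- sort(unique(trials$salinity_ppt))
  if (length(lev) < 2L)
    stop("need at least 2 distinct salinity levels")
  mean_rr <- vapply(lev, function(s) mean(rr[trials$salinity_ppt == s]),
                    numeric(1))
  if (max(mean_rr) <= 0)
    stop("all mean respiration rates are zero: curve undefined")
  suitability_curve("S_G", x = lev, si = mean_rr / max(mean_rr),
                    out_of_range = out_of_range)
}

#' Load a full curve set from a configuration file or list
#'
#' The configuration is a YAML (or JSON) mapping from each of the eight
#' variable identifiers to a list with `x`, `si` and optionally `policy`
#' entries. All eight variables must be present; each curve is validated
#' on construction.
#'
#' @param config path to a YAML/JSON file, or an already-parsed named list.
#' @return named list of [suitability_curve()] objects, one per variable,
#'   of class `hsi_curveset`.
#' @export
load_curveset <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("curve config not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("curve config must be a file path or a list")
  ids <- hsi_variable_ids()
  if (anyDuplicated(names(config)))
    stop("duplicate curve definition: ",
         paste(unique(names(config)[duplicated(names(config))]), collapse = ", "))
  miss <- setdiff(ids, names(config))
  if (length(miss))
    stop("missing curve: ", paste(miss, collapse = ", "))
  curves <- lapply(ids, function(id) {
    cf <- config[[id]]
    suitability_curve(id, x = cf$x, si = cf$si,
                      out_of_range = if (is.null(cf$policy)) "clamp_to_edge"
                                     else cf$policy)
  })
  names(curves) <- ids
  structure(curves, class = "hsi_curveset")
}

#' @export
print.hsi_curveset <- function(x, ...) {
  cat("HSI curve set:", length(x), "suitability curves\n")
  for (cv in x)
    cat(sprintf("  %-4s %d breakpoints over [%g, %g], peak SI %.2f\n",
                cv$variable_id, nrow(cv$breakpoints),
                min(cv$breakpoints$x), max(cv$breakpoints$x),
                max(cv$breakpoints$si)))
  invisible(x)
}

#' Bundled default suitability curves
#'
#' The package ships a documented default breakpoint set. The shapes follow
#' the ecology of subtropical intertidal rock oysters: settlement salinity
#' unsuitable below ~5 ppt and best above ~15 ppt; growth salinity near
#' zero at 0--5 ppt and maximal near 25--30 ppt; a pH optimum near
#' 7.9--8.5; suitability increasing with oxygen saturation; declining with
#' suspended inorganic sediment load; and increasing with chlorophyll-a as
#' a food proxy. These defaults are approximations intended as a working
#' starting point; site-specific studies should supply their own curve
#' configuration (see [load_curveset()]).
#'
#' @return an `hsi_curveset`.
#' @export
default_curveset <- function() {
  load_curveset(system.file("extdata", "default_curves.yaml",
                            package = "oysterHSI", mustWork = TRUE))
}
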