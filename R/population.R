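#' Oyster population descriptors from quadrat surveys
#'
#' Population surveys use fixed-area quadrats (default 25 cm x 25 cm =
#' 0.0625 m2) placed on intertidal substrate; live oysters are counted per
#' quadrat and a subset is measured individually (shell height, dry flesh
#' and dry shell weight). Quadrats without oysters count as zero and stay
#' in the density calculation. Dead shell remains are excluded before the
#' data reach this module.
#'
#' @name population
NULL

#' Oyster density per square metre
#'
#' Per-quadrat density is `live_count / area`; the site mean and sample
#' standard deviation are taken across all quadrats, zeros included.
#'
#' @param live_count integer vector of live oysters per quadrat.
#' @param area_m2 quadrat areas in m2 (scalar or per-quadrat vector).
#' @return list with `mean`, `sd` (NA for a single quadrat) and
#'   `n_quadrats`, densities in individuals per m2.
#' @examples
#' oyster_density(c(4, 0, 2, 6, 3), 0.0625)  # mean 48 ind/m2
#' @export
oyster_density <- function(live_count, area_m2 = 0.0625) {
  if (any(area_m2 <= 0)) stop("quadrat area must be > 0")
  if (any(live_count < 0)) stop("negative live count")
  if (length(live_count) == 0L) stop("no quadrats supplied")
  d <- live_count / area_m2
  list(mean = mean(d),
       sd = if (length(d) > 1L) stats::sd(d) else NA_real_,
       n_quadrats = length(d))
}

#' Condition index of an oyster
#'
#' Percentage ratio of dry flesh weight to dry shell weight,
#' `100 * dry_flesh / dry_shell` — a body-condition measure for bivalves
#' (typical field range roughly 4--11% for intertidal rock oysters).
#'
#' @param dry_flesh_g dry flesh weight (g), >= 0.
#' @param dry_shell_g dry shell weight (g), > 0.
#' @return condition index in percent (vectorised).
#' @examples
#' condition_index(0.6, 10)  # 6 %
#' @export
condition_index <- function(dry_flesh_g, dry_shell_g) {
  if (any(dry_shell_g <= 0)) stop("dry shell weight must be > 0")
  if (any(dry_flesh_g < 0)) stop("dry flesh weight must be >= 0")
  100 * dry_flesh_g / dry_shell_g
}

#' Per-site population summary
#'
#' Aggregates the three population descriptors for one or more sites:
#' density over all quadrats (zeros included), shell height and condition
#' index over the measured individuals only. The site condition index is
#' the mean of the individual flesh/shell ratios. Sites with oysters
#' counted but none measured keep `NA` height and condition index.
#'
#' @param quadrats data.frame with columns `site_id`, `quadrat_id`,
#'   `area_m2`, `live_count`.
#' @param individuals data.frame with columns `site_id`, `shell_height_cm`,
#'   `dry_flesh_g`, `dry_shell_g` (may be empty).
#' @return data.frame with one row per site: `site_id`, `density_mean`,
#'   `density_sd`, `height_mean`, `height_sd`, `cindex_mean`, `cindex_sd`,
#'   `n_quadrats`, `n_individuals`.
#' @export
site_summary <- function(quadrats, individuals = NULL) {
  req <- c("site_id", "quadrat_id", "area_m2", "live_count")
  miss <- setdiff(req, names(quadrats))
  if (length(miss))
    stop("quadrats missing columns: ", paste(miss, collapse = ", "))
  sites <- unique(quadrats$site_id)
  rows <- lapply(sites, function(s) {
    q <- quadrats[quadrats$site_id == s, , drop = FALSE]
    dens <- oyster_density(q$live_count, q$area_m2)
    hm <- hs <- cm <- cs <- NA_real_
    ni <- 0L
    if (!is.null(individuals)) {
      ind <- individuals[individuals$site_id == s, , drop = FALSE]
      ni <- nrow(ind)
      if (ni > 0L) {
        ci <- condition_index(ind$dry_flesh_g, ind$dry_shell_g)
        hm <- mean(ind$shell_height_cm)
        hs <- if (ni > 1L) stats::sd(ind$shell_height_cm) else NA_real_
        cm <- mean(ci)
        cs <- if (ni > 1L) stats::sd(ci) else NA_real_
      }
    }
    data.frame(site_id = s,
               density_mean = dens$mean, density_sd = dens$sd,
               height_mean = hm, height_sd = hs,
               cindex_mean = cm, cindex_sd = cs,
               n_quadrats = dens$n_quadrats, n_individuals = ni,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
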