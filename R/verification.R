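#' Pearson correlation with bootstrap quantile confidence bounds
#'
#' Sample Pearson correlation between two site-level vectors (e.g. HSI
#' score against mean oyster density) with 95% confidence bounds from a
#' paired nonparametric bootstrap: `B` resamples of the site pairs with
#' replacement, bounds at the 2.5 and 97.5 percentiles of the resampled
#' correlations. Degenerate resamples (zero variance after resampling)
#' are dropped from the quantiles.
#'
#' @param x,y numeric vectors of equal length (n >= 3), no missing values.
#' @param B number of bootstrap resamples (>= 200; default 1000).
#' @param seed integer seed, mandatory: all resampling is reproducible.
#' @return list with `r`, `n`, `ci_low`, `ci_high`, `B`.
#' @export
pearson_bootstrap <- function(x, y, B = 1000, seed) {
  if (missing(seed)) stop("a seed is required for the bootstrap")
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  if (B < 200L) stop("B must be at least 200")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y: correlation undefined")
  r <- stats::cor(x, y)
  set.seed(seed)
  rb <- vapply(seq_len(B), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) return(NA_real_)
    stats::cor(x[i], y[i])
  }, numeric(1))
  q <- stats::quantile(rb, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(r = r, n = n, ci_low = q[1L], ci_high = q[2L], B = B)
}

#' Forward-stepwise multiple linear regression
#'
#' SPSS-style forward selection with a removal check: at each step the
#' candidate predictor with the smallest entry p-value (partial t/F test)
#' below `alpha_enter` joins the model; included predictors whose p-value
#' rises above `alpha_remove` are dropped again. Selection stops when no
#' candidate qualifies. If nothing ever qualifies the intercept-only model
#' is returned.
#'
#' Reported summary statistics follow the conventional regression summary
#' table: multiple R, R-squared, adjusted R-squared, standard error of the
#' estimate, and the F-change of the final entry step with its degrees of
#' freedom and p-value. Variance inflation factors are reported per
#' selected predictor and flagged at `vif_limit` (default 5); aliased
#' (perfectly collinear) predictors get infinite VIF.
#'
#' @param data data.frame containing the response and predictors.
#' @param response name of the response column.
#' @param predictors candidate predictor names (default: the seven model
#'   variables `T`, `S`, `pH`, `DO`, `PIM`, `Chla`, `V` if present,
#'   otherwise all non-response columns).
#' @param alpha_enter entry significance level (default 0.05).
#' @param alpha_remove removal significance level (default 0.10).
#' @param force_in predictors always kept in the model.
#' @param vif_limit collinearity flag threshold.
#' @return object of class `stepwise_fit`: list with `model` (the `lm`
#'   fit), `selected`, `coefficients`, `R`, `r_squared`, `adj_r_squared`,
#'   `sigma`, `f_change`, `df1`, `df2`, `sig_f`, `vif`, `vif_flag`,
#'   `steps` (entry/removal log), `n`.
#' @export
stepwise_regression <- function(data, response,
                                predictors = NULL,
                                alpha_enter = 0.05, alpha_remove = 0.10,
                                force_in = character(),
                                vif_limit = 5) {
  stopifnot(response %in% names(data))
  if (is.null(predictors)) {
    std <- c("T", "S", "pH", "DO", "PIM", "Chla", "V")
    predictors <- if (all(std %in% names(data))) std
                  else setdiff(names(data), response)
  }
  miss <- setdiff(c(predictors, force_in), names(data))
  if (length(miss)) stop("predictors not in data: ", paste(miss, collapse = ", "))
  n <- nrow(data)
  if (n <= length(predictors) + 2L)
    warning("few observations relative to candidate predictors")

  fit_with <- function(vars) {
    fm <- if (length(vars))
      stats::reformulate(sprintf("`%s`", vars), response = sprintf("`%s`", response))
    else stats::reformulate("1", response = sprintf("`%s`", response))
    stats::lm(fm, data = data)
  }
  # coefficient row for a variable (backticks are kept only for
  # non-syntactic names)
  coef_row <- function(ct, v) {
    rn <- intersect(c(v, sprintf("`%s`", v)), rownames(ct))
    if (length(rn)) rn[1L] else NA_character_
  }
  entry_p <- function(current, cand) {
    f1 <- fit_with(c(current, cand))
    ct <- summary(f1)$coefficients
    rn <- coef_row(ct, cand)
    if (is.na(rn)) return(NA_real_)  # aliased with current model
    ct[rn, 4L]
  }

  included <- unique(force_in)
  steps <- list()
  last_entry <- NULL
  repeat {
    cands <- setdiff(predictors, included)
    pvals <- vapply(cands, function(v) entry_p(included, v), numeric(1))
    ok <- which(!is.na(pvals) & pvals < alpha_enter)
    if (!length(ok)) break
    best <- cands[ok[which.min(pvals[ok])]]
    included <- c(included, best)
    last_entry <- best
    steps[[length(steps) + 1L]] <- list(action = "enter", variable = best,
                                        p = min(pvals[ok]))
    # removal pass (never removes forced-in predictors)
    repeat {
      fit <- fit_with(included)
      ct <- summary(fit)$coefficients
      rem <- setdiff(included, c(force_in, last_entry))
      if (!length(rem)) break
      rp <- vapply(rem, function(v) {
        rn <- coef_row(ct, v)
        if (is.na(rn)) return(Inf)
        ct[rn, 4L]
      }, numeric(1))
      worst <- which.max(rp)
      if (rp[worst] <= alpha_remove) break
      steps[[length(steps) + 1L]] <- list(action = "remove",
                                          variable = rem[worst],
                                          p = rp[worst])
      included <- setdiff(included, rem[worst])
    }
  }

  fit <- fit_with(included)
  sm <- summary(fit)
  # F-change of the final entry step: squared t of the last entered term
  f_change <- df1 <- df2 <- sig_f <- NA_real_
  if (!is.null(last_entry)) {
    rn <- coef_row(sm$coefficients, last_entry)
    if (!is.na(rn)) {
      tval <- sm$coefficients[rn, 3L]
      f_change <- tval^2
      df1 <- 1
      df2 <- fit$df.residual
      sig_f <- sm$coefficients[rn, 4L]
    }
  }
  vifs <- compute_vif(fit, included)
  structure(list(
    model = fit,
    response = response,
    selected = included,
    coefficients = stats::coef(fit),
    R = sqrt(sm$r.squared),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    sigma = sm$sigma,
    f_change = f_change, df1 = df1, df2 = df2, sig_f = sig_f,
    vif = vifs, vif_flag = any(!is.na(vifs) & vifs >= vif_limit),
    steps = steps, n = n), class = "stepwise_fit")
}

compute_vif <- function(fit, included) {
  if (length(included) == 0L) return(numeric(0))
  if (length(included) == 1L)
    return(stats::setNames(1, included))
  if (any(is.na(stats::coef(fit))))  # aliased: perfect collinearity
    return(stats::setNames(rep(Inf, length(included)), included))
  v <- tryCatch(car::vif(fit),
                error = function(e)
                  stats::setNames(rep(Inf, length(included)), included))
  stats::setNames(as.numeric(v), included)
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("Forward-stepwise linear model for", x$response, "\n")
  cat("  selected:",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(intercept only)", "\n")
  cat(sprintf("  R = %.3f  R2 = %.3f  adj R2 = %.3f  SE = %.4f\n",
              x$R, x$r_squared, x$adj_r_squared, x$sigma))
  if (!is.na(x$f_change))
    cat(sprintf("  F change = %.3f (df %d, %d), p = %.4g\n",
                x$f_change, x$df1, x$df2, x$sig_f))
  if (length(x$vif)) {
    cat("  VIF:", paste(sprintf("%s=%.2f", names(x$vif), x$vif),
                        collapse = ", "),
        if (x$vif_flag) " [collinearity flag]" else "", "\n")
  }
  invisible(x)
}

#' Residual diagnostics for a fitted regression
#'
#' Normality of residuals by the Lilliefors-corrected Kolmogorov--Smirnov
#' test (parameters estimated from the residuals), and homogeneity of
#' variance by Levene's test across fitted-value tertile groups.
#'
#' @param fit an `lm` object or a `stepwise_fit`.
#' @return list with `ks_p`, `levene_p`, and `skipped` (TRUE with both
#'   p-values NA when there are fewer than 6 residuals).
#' @export
regression_diagnostics <- function(fit) {
  if (inherits(fit, "stepwise_fit")) fit <- fit$model
  res <- stats::residuals(fit)
  if (length(res) < 6L)
    return(list(ks_p = NA_real_, levene_p = NA_real_, skipped = TRUE))
  ks_p <- nortest::lillie.test(res)$p.value
  grp <- cut(stats::fitted(fit),
             breaks = stats::quantile(stats::fitted(fit),
                                      probs = c(0, 1/3, 2/3, 1)),
             include.lowest = TRUE, labels = FALSE)
  if (length(unique(grp)) < 2L) {
    lev_p <- NA_real_
  } else {
    lev <- car::leveneTest(res, group = factor(grp))
    lev_p <- lev[["Pr(>F)"]][1L]
  }
  list(ks_p = ks_p, levene_p = lev_p, skipped = FALSE)
}

#' Verify HSI scores against population descriptors
#'
#' Convenience wrapper correlating station HSI with each population
#' descriptor (density, shell height, condition index) via
#' [pearson_bootstrap()], and reporting the minimum HSI among sites with
#' non-zero observed density.
#'
#' @param hsi_table output of [hsi_pipeline()] (needs `station_id`, `hsi`).
#' @param pop_table output of [site_summary()] (keyed by `site_id`).
#' @param B,seed bootstrap parameters, see [pearson_bootstrap()].
#' @return data.frame with one row per descriptor: `descriptor`, `r`, `n`,
#'   `ci_low`, `ci_high`; attribute `min_hsi_with_oysters`.
#' @export
verify_hsi <- function(hsi_table, pop_table, B = 1000, seed) {
  merged <- merge(hsi_table[, c("station_id", "hsi")], pop_table,
                  by.x = "station_id", by.y = "site_id")
  if (nrow(merged) < 3L) stop("fewer than 3 sites in common")
  desc <- c(density = "density_mean", shell_height = "height_mean",
            condition_index = "cindex_mean")
  rows <- lapply(names(desc), function(d) {
    keep <- is.finite(merged[[desc[[d]]]])
    pb <- pearson_bootstrap(merged$hsi[keep], merged[[desc[[d]]]][keep],
                            B = B, seed = seed)
    data.frame(descriptor = d, r = pb$r, n = pb$n,
               ci_low = pb$ci_low, ci_high = pb$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  occupied <- merged$density_mean > 0
  attr(out, "min_hsi_with_oysters") <-
    if (any(occupied)) min(merged$hsi[occupied]) else NA_real_
  out
}
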