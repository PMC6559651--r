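test_that("curve construction enforces the invariants", {
  expect_error(suitability_curve("S_G", x = c(0, 10), si = c(0, 1.2)),
               "\\[0, 1\\]")
  expect_error(suitability_curve("S_G", x = c(10, 0), si = c(0, 1)),
               "strictly increasing")
  expect_error(suitability_curve("S_G", x = 5, si = 1), "at least 2")
  expect_error(suitability_curve("S_G", x = c(0, NA), si = c(0, 1)),
               "finite")
  cv <- suitability_curve("S_G", x = c(0, 10, 35), si = c(0, 1, 1))
  expect_s3_class(cv, "suitability_curve")
})

test_that("curve evaluation: breakpoints, interior points, range policies", {
  cv <- suitability_curve("S_G", x = c(0, 10, 35), si = c(0, 1, 1))
  expect_identical(eval_suitability(cv, 10), 1.0)
  expect_identical(eval_suitability(cv, 5), 0.5)
  expect_identical(eval_suitability(cv, 40), 1.0)   # clamp above
  expect_identical(eval_suitability(cv, -5), 0.0)   # clamp below (edge si 0)
  cz <- suitability_curve("S_G", x = c(5, 10), si = c(0.4, 1),
                          out_of_range = "zero")
  expect_identical(eval_suitability(cz, c(0, 5, 12)), c(0, 0.4, 0))
  expect_error(eval_suitability(cv, NaN), "non-finite")
  expect_error(eval_suitability(cv, Inf), "non-finite")
})

test_that("evaluation agrees with a brute-force interpolation oracle", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    xs <- sort(runif(n, 0, 40))
    while (any(diff(xs) < 1e-6)) xs <- sort(runif(n, 0, 40))
    sis <- runif(n)
    cv <- suitability_curve("PIM", x = xs, si = sis)
    grid <- runif(200, min(xs) - 5, max(xs) + 5)
    got <- eval_suitability(cv, grid)
    want <- oracle_interp(xs, sis, grid)
    expect_lt(max(abs(got - want)), 1e-12)
  }
})

test_that("respiration rate follows the closed-chamber equation", {
  expect_equal(respiration_rate(1, 6.0, 5.0, 2), 0.5)
  expect_equal(respiration_rate(1, 6.0, 6.0, 2), 0)
  expect_equal(respiration_rate(0.5, 6.4, 5.2, 1.5), 0.4)
  # linear in chamber volume and in the oxygen drop
  base <- respiration_rate(1, 6, 5, 2)
  expect_equal(respiration_rate(3, 6, 5, 2), 3 * base)
  expect_equal(respiration_rate(1, 6, 4, 2), 2 * base)
  expect_error(respiration_rate(0, 6, 5, 2), "chamber_volume")
  expect_error(respiration_rate(1, 6, 5, 0), "duration")
  expect_warning(respiration_rate(1, 6, 2.0, 2), "oxygen-limited")
})

test_that("salinity-curve calibration normalises mean rates to peak 1", {
  mk <- function(sal, rate) data.frame(
    salinity_ppt = sal, volume_l = 1, po2_start_ml_l = 6,
    po2_end_ml_l = 6 - rate * 2, duration_h = 2)
  # mean rates {0: 0, 15: 0.4, 30: 0.8} -> si {0, 0.5, 1}
  tr <- rbind(mk(0, 0), mk(15, 0.4), mk(30, 0.8))
  cv <- calibrate_salinity_curve(tr)
  expect_equal(cv$breakpoints$x, c(0, 15, 30))
  expect_equal(cv$breakpoints$si, c(0, 0.5, 1))
  # equal nonzero rates -> all si = 1
  tr2 <- rbind(mk(0, 0.3), mk(20, 0.3), mk(35, 0.3))
  expect_equal(calibrate_salinity_curve(tr2)$breakpoints$si, c(1, 1, 1))
  # {0: 0.2, 20: 1.0, 35: 0.2} -> 0.2 at extremes
  tr3 <- rbind(mk(0, 0.2), mk(35, 0.2), mk(20, 1.0))
  expect_equal(calibrate_salinity_curve(tr3)$breakpoints$si, c(0.2, 1, 0.2))
  # replicates averaged within level before normalisation
  tr4 <- rbind(mk(10, 0.2), mk(10, 0.6), mk(25, 0.8))
  expect_equal(calibrate_salinity_curve(tr4)$breakpoints$si, c(0.5, 1))
  expect_error(calibrate_salinity_curve(rbind(mk(0, 0), mk(10, 0))),
               "zero")
  expect_error(calibrate_salinity_curve(mk(10, 0.5)), "2 distinct")
})

test_that("calibrated curves attain si = 1 exactly at argmax levels", {
  set.seed(202)
  for (rep in 1:10) {
    sal <- seq(0, 35, by = 5)
    rates <- runif(8, 0.05, 1)
    tr <- data.frame(salinity_ppt = rep(sal, each = 3), volume_l = 1,
                     po2_start_ml_l = 6,
                     po2_end_ml_l = 6 - rep(rates, each = 3) * 2,
                     duration_h = 2)
    cv <- calibrate_salinity_curve(tr)
    expect_equal(max(cv$breakpoints$si), 1)
    expect_equal(which(cv$breakpoints$si == 1), which.max(rates))
  }
})

test_that("curve-set loading validates completeness and content", {
  cs <- default_curveset()
  expect_s3_class(cs, "hsi_curveset")
  expect_setequal(names(cs), hsi_variable_ids())
  for (cv in cs) {
    expect_true(all(diff(cv$breakpoints$x) > 0))
    expect_true(all(cv$breakpoints$si >= 0 & cv$breakpoints$si <= 1))
    expect_gte(nrow(cv$breakpoints), 2)
  }
  cfg <- lapply(cs, function(cv) list(x = cv$breakpoints$x,
                                      si = cv$breakpoints$si))
  expect_error(load_curveset(cfg[setdiff(names(cfg), "PIM")]),
               "missing curve: PIM")
  bad <- cfg
  bad$pH$si[1] <- 1.2
  expect_error(load_curveset(bad), "\\[0, 1\\]")
  expect_error(load_curveset("no/such/file.yaml"), "not found")
})
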