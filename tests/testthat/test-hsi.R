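mk_si <- function(Ss = 1, V = 1, T = 1, Sg = 1, pH = 1, DO = 1,
                  PIM = 1, Chla = 1) {
  c(si_Ss = Ss, si_V = V, si_T = T, si_Sg = Sg, si_pH = pH, si_DO = DO,
    si_PIM = PIM, si_Chla = Chla)
}

test_that("settlement CI: per-season geometric mean, seasons averaged", {
  expect_equal(ci_settlement(mk_si(), mk_si())$ci, 1)
  # a zero settlement season halves, not zeroes, the stage
  r <- ci_settlement(mk_si(Ss = 0), mk_si())
  expect_equal(r$ci_m, 0)
  expect_equal(r$ci, 0.5)
  r2 <- ci_settlement(mk_si(Ss = 0.25), mk_si(Ss = 0.81))
  expect_equal(r2$ci_m, 0.5)
  expect_equal(r2$ci_nm, 0.9)
  expect_equal(r2$ci, 0.7)
})

test_that("post-settlement CI: six-way geometric mean, zero propagation", {
  expect_equal(ci_post_settlement(mk_si(), mk_si())$ci, 1)
  expect_equal(ci_post_settlement(mk_si(), mk_si(), "as_printed")$ci, 1)
  # any zero SI in either season zeroes the stage
  for (z in c("Sg", "PIM", "Chla")) {
    args <- stats::setNames(list(0), z)
    zi <- do.call(mk_si, args)
    expect_equal(ci_post_settlement(zi, mk_si())$ci, 0)
    expect_equal(ci_post_settlement(mk_si(), zi)$ci, 0)
    expect_equal(ci_post_settlement(zi, mk_si(), "as_printed")$ci, 0)
  }
})

test_that("cross-season exponent modes differ as documented", {
  si_nm <- mk_si(Sg = 0.512^6)  # makes ci_nm = 0.512
  rn <- ci_post_settlement(mk_si(), si_nm, "normalized")
  rp <- ci_post_settlement(mk_si(), si_nm, "as_printed")
  expect_equal(rn$ci_nm, 0.512)
  expect_equal(rn$ci, 0.512^(2 / 3))
  expect_equal(rn$ci, 0.64)
  expect_equal(rp$ci, 0.512^(1 / 3))
  expect_equal(rp$ci, 0.8)
  # equal seasonal CIs: normalized returns that CI, as_printed inflates
  si_c <- mk_si(Sg = 0.5)
  rn2 <- ci_post_settlement(si_c, si_c, "normalized")
  rp2 <- ci_post_settlement(si_c, si_c, "as_printed")
  expect_equal(rn2$ci, rn2$ci_m)
  expect_equal(rp2$ci, rp2$ci_m^(2 / 3))
  expect_gte(rp2$ci, rp2$ci_m)
})

test_that("HSI combination: minimum-limiting rule with geometric branch", {
  expect_equal(combine_hsi(0.6, 0.4), 0.4)
  expect_equal(combine_hsi(0.49, 0.81), 0.63)
  expect_equal(combine_hsi(0.5, 0.5), 0.5)
  expect_equal(combine_hsi(0, 1), 0)
  expect_equal(combine_hsi(1, 0), 0)
})

test_that("suitability categories split at 0.3 and 0.5", {
  expect_equal(hsi_category(c(0.51, 0.5, 0.31, 0.3, 0)),
               c("suitable", "less_suitable", "less_suitable",
                 "least_suitable", "least_suitable"))
  expect_error(hsi_category(1.2), "\\[0, 1\\]")
})

test_that("increasing any single SI never decreases the HSI", {
  set.seed(77)
  full_hsi <- function(si_m, si_nm, mode) {
    combine_hsi(ci_settlement(si_m, si_nm)$ci,
                ci_post_settlement(si_m, si_nm, mode)$ci)
  }
  for (rep in 1:30) {
    si_m <- mk_si(); si_m[] <- runif(8)
    si_nm <- mk_si(); si_nm[] <- runif(8)
    k <- sample(8, 1); season <- sample(c("m", "nm"), 1)
    bump <- function(si) { si[k] <- min(1, si[k] + runif(1, 0, 0.5)); si }
    for (mode in c("normalized", "as_printed")) {
      h0 <- full_hsi(si_m, si_nm, mode)
      h1 <- if (season == "m") full_hsi(bump(si_m), si_nm, mode)
            else full_hsi(si_m, bump(si_nm), mode)
      expect_gte(h1, h0 - 1e-12)
      expect_gte(h0, 0); expect_lte(h0, 1 + 1e-12)
    }
  }
})

test_that("SI vectors evaluate curves at seasonal means, salinity twice", {
  cs <- default_curveset()
  means <- c(temperature = 27, salinity = 20, do_sat = 80, ph = 8.0,
             chla = 4, pim = 150, velocity = 0.5)
  si <- si_vector(means, cs)
  expect_equal(si[["si_Ss"]], eval_suitability(cs$Ss, 20))
  expect_equal(si[["si_Sg"]], eval_suitability(cs$S_G, 20))
  expect_equal(si[["si_PIM"]], eval_suitability(cs$PIM, 150))
  expect_true(all(si >= 0 & si <= 1))
  means_bad <- means; means_bad[["chla"]] <- NA
  expect_error(si_vector(means_bad, cs, station = "S007"),
               "S007.*chla")
})

test_that("pipeline stations at curve optima / zero salinity behave analytically", {
  cs <- default_curveset()
  opt <- c(temperature = 27, salinity = 25, do_sat = 90, ph = 8.1,
           chla = 6, pim = 50, velocity = 0.5)
  rec <- station_records("OPT", opt, opt)
  res <- hsi_pipeline(rec, cs)
  expect_equal(res$hsi, 1)
  expect_equal(res$category, "suitable")
  # monsoon salinity 0 -> si_Sg = 0 -> hsi 0 regardless of the rest
  fresh <- opt; fresh[["salinity"]] <- 0
  rec2 <- station_records("FRW", fresh, opt)
  res2 <- hsi_pipeline(rec2, cs)
  expect_equal(res2$hsi, 0)
  expect_equal(res2$category, "least_suitable")
})

test_that("pipeline equals an independent brute-force recomputation", {
  cs <- default_curveset()
  set.seed(55)
  recs <- do.call(rbind, lapply(1:5, function(i) {
    m <- c(temperature = runif(1, 27, 28.6), salinity = runif(1, 0.5, 29),
           do_sat = runif(1, 49, 91), ph = runif(1, 7.4, 8.5),
           chla = runif(1, 0.8, 9.6), pim = runif(1, 21, 1000),
           velocity = runif(1, 0.2, 2.4))
    nm <- m + c(runif(1, -0.5, 0.5), runif(1, 0, 5), runif(1, -5, 5),
                runif(1, -0.2, 0.2), runif(1, 0, 2), runif(1, -50, 50),
                runif(1, -0.1, 0.1))
    station_records(sprintf("F%02d", i), m, nm)
  }))
  # add tidal duplicates to exercise the collapse step
  dup <- recs[recs$date == as.Date("2016-06-15"), ]
  dup$salinity_ppt <- dup$salinity_ppt + 2
  recs <- rbind(recs, dup)
  for (mode in c("normalized", "as_printed")) {
    got <- hsi_pipeline(recs, cs, weight_mode = mode)
    want <- oracle_hsi(recs, cs, weight_mode = mode)
    expect_lt(max(abs(got$hsi - want[got$station_id])), 1e-12)
  }
})
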