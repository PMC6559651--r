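test_that("bootstrap correlation: exact cases, errors, reproducibility", {
  x <- seq_len(20)
  expect_equal(pearson_bootstrap(x, 2 * x + 1, B = 200, seed = 1)$r, 1)
  expect_error(pearson_bootstrap(x, rep(3, 20), B = 200, seed = 1),
               "zero variance")
  expect_error(pearson_bootstrap(x[1:2], x[1:2], B = 200, seed = 1),
               "at least 3")
  expect_error(pearson_bootstrap(x, 2 * x, B = 50, seed = 1), "at least 200")
  expect_error(pearson_bootstrap(x, 2 * x), "seed")
  set.seed(9); y <- x + rnorm(20, 0, 4)
  a <- pearson_bootstrap(x, y, B = 500, seed = 42)
  b <- pearson_bootstrap(x, y, B = 500, seed = 42)
  expect_identical(a, b)                      # bit-reproducible
  expect_lte(a$ci_low, a$r)
  expect_gte(a$ci_high, a$r)
})

test_that("bootstrap correlation is affine-invariant up to sign", {
  set.seed(14)
  x <- rnorm(40); y <- 0.8 * x + rnorm(40, 0, 0.5)
  base <- pearson_bootstrap(x, y, B = 300, seed = 5)
  shifted <- pearson_bootstrap(3 * x + 10, 0.5 * y - 2, B = 300, seed = 5)
  expect_equal(shifted$r, base$r)
  expect_equal(shifted$ci_low, base$ci_low)
  flipped <- pearson_bootstrap(-x, y, B = 300, seed = 5)
  expect_equal(flipped$r, -base$r)
})

test_that("independent data give small r with CI usually spanning zero", {
  set.seed(21)
  hits <- 0; reps <- 40
  for (i in 1:reps) {
    pb <- pearson_bootstrap(rnorm(50), rnorm(50), B = 400, seed = i)
    if (pb$ci_low <= 0 && pb$ci_high >= 0) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("forward stepwise selects a strongly associated predictor first", {
  set.seed(33)
  n <- 60
  X <- as.data.frame(matrix(rnorm(n * 7), n,
                            dimnames = list(NULL, c("T", "S", "pH", "DO",
                                                    "PIM", "Chla", "V"))))
  X$y <- 3 * X$S + rnorm(n)
  fit <- stepwise_regression(X, "y")
  expect_equal(fit$steps[[1]]$variable, "S")
  expect_true("S" %in% fit$selected)
  expect_true(all(fit$vif >= 1 - 1e-9))
  expect_equal(fit$df1, 1)
  expect_lte(fit$sig_f, 0.05)
  expect_gte(fit$adj_r_squared, 0)
  expect_lte(fit$adj_r_squared, fit$r_squared)
})

test_that("nothing qualifying yields the intercept-only model", {
  set.seed(44)
  d <- data.frame(y = rnorm(30), a = rep(c(0.1, 0.2), 15))
  # predictor orthogonal-ish to y by chance is not guaranteed; force it:
  d$a <- rep(0.15, 30) + c(rep(0, 29), 1e-9)
  fit <- stepwise_regression(d, "y", predictors = "a", alpha_enter = 1e-12)
  expect_length(fit$selected, 0)
  expect_equal(unname(fit$coefficients["(Intercept)"]), mean(d$y))
  expect_equal(fit$r_squared, 0)
})

test_that("a duplicated forced-in column raises the collinearity flag", {
  set.seed(55)
  d <- data.frame(y = rnorm(40), x1 = rnorm(40))
  d$x2 <- d$x1  # perfect collinearity
  fit <- stepwise_regression(d, "y", predictors = character(),
                             force_in = c("x1", "x2"))
  expect_true(fit$vif_flag)
  expect_true(all(is.infinite(fit$vif)))
})

test_that("removal step drops predictors that lose significance", {
  # x1 and x2 highly correlated; y driven by their sum. After both-ish
  # candidates compete, the removal rule keeps the model consistent with
  # alpha_remove.
  set.seed(66)
  n <- 80
  x1 <- rnorm(n); x2 <- x1 + rnorm(n, 0, 0.1); x3 <- rnorm(n)
  y <- x1 + rnorm(n, 0, 0.5)
  d <- data.frame(y, x1, x2, x3)
  fit <- stepwise_regression(d, "y", predictors = c("x1", "x2", "x3"))
  # at most one of the twins survives
  expect_lte(sum(c("x1", "x2") %in% fit$selected), 1)
})

test_that("diagnostics report normality and variance-homogeneity p-values", {
  set.seed(88)
  n <- 120
  d <- data.frame(x = rnorm(n))
  d$y <- 2 * d$x + rnorm(n)
  fit <- stepwise_regression(d, "y", predictors = "x")
  dg <- regression_diagnostics(fit)
  expect_false(dg$skipped)
  expect_gt(dg$ks_p, 0.001)     # normal residuals: should not reject hard
  expect_gt(dg$levene_p, 0.001)
  # heavy-tailed residuals are detected with decent power
  set.seed(89)
  rejections <- 0
  for (i in 1:20) {
    d2 <- data.frame(x = rnorm(200))
    d2$y <- d2$x + rt(200, df = 2)
    f2 <- stats::lm(y ~ x, data = d2)
    if (regression_diagnostics(f2)$ks_p < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections / 20, 0.8)
  # tiny samples are skipped with a flag
  tiny <- stats::lm(y ~ x, data = d[1:5, ])
  expect_true(regression_diagnostics(tiny)$skipped)
})

test_that("verify_hsi correlates HSI with descriptors over merged sites", {
  sites <- gen_verification_sites(n = 53, seed = 10)
  hsi_tab <- data.frame(station_id = sites$site_id, hsi = sites$true_hsi)
  pop <- data.frame(site_id = sites$site_id,
                    density_mean = sites$density_mean,
                    height_mean = sites$height_mean,
                    cindex_mean = sites$cindex_mean)
  v <- verify_hsi(hsi_tab, pop, B = 400, seed = 3)
  expect_setequal(v$descriptor,
                  c("density", "shell_height", "condition_index"))
  expect_true(all(v$n == 53))
  expect_true(all(v$r > 0.7))
  expect_true(all(v$ci_low <= v$r & v$r <= v$ci_high))
})
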