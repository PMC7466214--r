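test_that("noiseless points on a known line are recovered exactly", {
  s <- line_series(1.3579, -0.0011, c(0.0025, 0.01, 0.05, 0.1, 0.5, 1, 2),
                   replicates = 3)
  f <- fit_calibration(s)
  expect_equal(f$slope, 1.3579, tolerance = 1e-12)
  expect_equal(f$intercept, -0.0011, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)

  f2 <- fit_calibration(data.frame(concentration = c(0, 1),
                                   response_ratio = c(0, 1)))
  expect_equal(f2$slope, 1)
  expect_equal(f2$intercept, 0)
  expect_equal(f2$r_squared, 1)
})

test_that("OLS coefficients equal the normal-equations oracle on noisy data", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    x <- runif(n, 0, 2)
    y <- 1.5 * x - 0.02 + rnorm(n, sd = 0.05)
    f <- fit_calibration(data.frame(concentration = x, response_ratio = y))
    o <- ols_oracle(x, y)
    expect_equal(f$slope, unname(o["slope"]), tolerance = 1e-10)
    expect_equal(f$intercept, unname(o["intercept"]), tolerance = 1e-10)
  }
})

test_that("calibration fit is invariant to point order and series duplication", {
  set.seed(7)
  s <- line_series(2, 0.1, c(0.1, 0.5, 1, 2))
  s$response_ratio <- s$response_ratio + rnorm(nrow(s), sd = 0.01)
  f1 <- fit_calibration(s)
  f2 <- fit_calibration(s[sample(nrow(s)), ])
  f3 <- fit_calibration(rbind(s, s))
  expect_equal(f1$slope, f2$slope)
  expect_equal(f1$intercept, f2$intercept)
  expect_equal(f1$slope, f3$slope, tolerance = 1e-12)
  expect_equal(f1$intercept, f3$intercept, tolerance = 1e-12)
})

test_that("R-squared is 1 iff residuals vanish", {
  exact <- line_series(1.2, 0.3, c(0, 0.5, 1, 2))
  expect_equal(fit_calibration(exact)$r_squared, 1, tolerance = 1e-12)
  noisy <- exact
  noisy$response_ratio[2] <- noisy$response_ratio[2] + 0.1
  expect_lt(fit_calibration(noisy)$r_squared, 1 - 1e-6)
  expect_error(fit_calibration(data.frame(concentration = c(1, 1),
                                          response_ratio = c(1, 2))),
               "degenerate", class = "fcm_domain_error")
})

test_that("LOD/LOQ are the lowest levels strictly above the S/N thresholds", {
  sn <- data.frame(concentration = c(0.0005, 0.001, 0.0025, 0.005),
                   sn_qual = c(2, 4, 12, 30),
                   sn_quant = c(1, 6, 11, 40))
  lim <- estimate_lod_loq(sn)
  expect_equal(lim$lod, 0.001)
  expect_equal(lim$loq, 0.0025)
  expect_true(lim$lod_reached && lim$loq_reached)

  # everything above both thresholds: both limits at the lowest level tested
  hi <- data.frame(concentration = c(0.001, 0.01), sn_qual = c(50, 500),
                   sn_quant = c(50, 500))
  lim2 <- estimate_lod_loq(hi)
  expect_equal(lim2$lod, 0.001)
  expect_equal(lim2$loq, 0.001)

  # quantification threshold never exceeded: LOQ flagged not reached
  low <- data.frame(concentration = c(0.001, 0.01), sn_qual = c(5, 8),
                    sn_quant = c(2, 9))
  lim3 <- estimate_lod_loq(low)
  expect_false(lim3$loq_reached)
  expect_true(is.na(lim3$loq))

  # boundary is strict: S/N exactly at the threshold does not qualify
  edge <- data.frame(concentration = c(0.001, 0.01), sn_qual = c(3, 4),
                     sn_quant = c(10, 11))
  lim4 <- estimate_lod_loq(edge)
  expect_equal(lim4$lod, 0.01)
  expect_equal(lim4$loq, 0.01)

  expect_error(estimate_lod_loq(sn[c(3, 1, 2, 4), ]),
               class = "fcm_domain_error")
})

test_that("raising an S/N threshold never lowers the returned limit", {
  set.seed(11)
  for (i in 1:25) {
    conc <- sort(runif(6, 0.0005, 0.05))
    sn <- data.frame(concentration = conc,
                     sn_qual = sort(runif(6, 0, 30)),
                     sn_quant = sort(runif(6, 0, 30)))
    as_inf <- function(x) if (is.na(x)) Inf else x
    t1 <- runif(1, 1, 10); t2 <- t1 + runif(1, 0, 10)
    lo <- suppressWarnings(estimate_lod_loq(sn, sn_quant_threshold = t1,
                                            sn_qual_threshold = t1))
    hi <- suppressWarnings(estimate_lod_loq(sn, sn_quant_threshold = t2,
                                            sn_qual_threshold = t2))
    expect_gte(as_inf(hi$loq), as_inf(lo$loq))
    expect_gte(as_inf(hi$lod), as_inf(lo$lod))
  }
})

test_that("repeatability RSD matches the hand-computed definition", {
  expect_equal(repeatability_rsd(c(0.1, 0.1, 0.1))$rsd_percent, 0)
  r <- repeatability_rsd(c(0.09, 0.10, 0.11))
  expect_equal(r$rsd_percent, 10)  # sd 0.01, mean 0.10
  expect_equal(r$n, 3)
  expect_error(repeatability_rsd(0.1), class = "fcm_domain_error")
  expect_error(repeatability_rsd(c(-1, 1)), class = "fcm_domain_error")
})
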