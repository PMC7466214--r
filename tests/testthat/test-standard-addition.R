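test_that("standard-addition fit and x-intercept behave on exact lines", {
  f <- fit_addition(data.frame(spike_level = c(0, 1),
                               response_ratio = c(1, 2)))
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 1)
  expect_equal(native_concentration(f), 1)

  # replicate duplication leaves the coefficients unchanged
  s <- addition_line(1.8, 0.36)
  expect_equal(fit_addition(rbind(s, s))$slope, fit_addition(s)$slope,
               tolerance = 1e-12)

  expect_error(fit_addition(data.frame(spike_level = c(0.05, 0.1),
                                       response_ratio = c(1, 2))),
               "unspiked", class = "fcm_domain_error")
  neg <- fit_addition(addition_line(1, -0.2))
  expect_warning(v <- native_concentration(neg), "negative")
  expect_equal(v, 0)
  falling <- fit_addition(addition_line(-0.5, 1))
  expect_error(native_concentration(falling), class = "fcm_domain_error")
})

test_that("x-intercept is invariant to multiplicative matrix effects", {
  set.seed(42)
  for (i in 1:25) {
    true_c <- runif(1, 0.02, 0.6)
    slope <- runif(1, 0.5, 3)
    base <- addition_line(slope, slope * true_c)
    k <- runif(1, 0.1, 10)
    scaled <- base
    scaled$response_ratio <- scaled$response_ratio * k
    expect_equal(native_concentration(fit_addition(scaled)),
                 native_concentration(fit_addition(base)),
                 tolerance = 1e-9)
  }
})

test_that("recovery is the matrix/solvent slope ratio in common units", {
  expect_equal(recovery_percent(1.0, 1.0), 100)
  expect_equal(recovery_percent(0.98 * 0.329 / 0.329 * 1.8091, 1.8091), 98)
  expect_equal(recovery_percent(0.72, 1.0), 72)
  # extract factor makes the slopes commensurate
  u2 <- units_config(extract_factor = 2)
  expect_equal(recovery_percent(0.5, 1.0, u2), 100)
  expect_error(recovery_percent(1, 0), class = "fcm_domain_error")
})

test_that("blank subtraction is a floored difference", {
  expect_equal(blank_subtract(0.10, 0.02), 0.08)
  expect_equal(blank_subtract(0.10, 0), 0.10)
  expect_equal(blank_subtract(0.02, 0.10), 0)
  expect_error(blank_subtract(-0.1, 0), class = "fcm_domain_error")
})

test_that("censoring substitutes LOQ/2 between the limits", {
  r <- censor_value(0.015, lod = 0.01, loq = 0.025)
  expect_equal(r$reported_value, 0.0125)
  expect_equal(r$censor_status, "below_loq")

  at_loq <- censor_value(0.025, lod = 0.01, loq = 0.025)
  expect_equal(at_loq$censor_status, "quantified")
  expect_equal(at_loq$reported_value, 0.025)

  below <- censor_value(0.001, lod = 0.01, loq = 0.025)
  expect_equal(below$reported_value, 0)
  expect_equal(below$censor_status, "below_lod")
  mid <- censor_value(0.001, lod = 0.01, loq = 0.025,
                      below_lod = "half_lod")
  expect_equal(mid$reported_value, 0.005)

  expect_error(censor_value(0.1, lod = 0.05, loq = 0.01),
               class = "fcm_validation_error")
})

test_that("censoring is idempotent with a non-decreasing status class", {
  set.seed(13)
  rank <- c(quantified = 0, below_loq = 1, below_lod = 2)
  for (i in 1:50) {
    lod <- runif(1, 0.001, 0.05)
    loq <- lod * runif(1, 2, 5)
    c0 <- runif(1, 0, 2 * loq)
    r1 <- censor_value(c0, lod, loq)
    r2 <- censor_value(r1$reported_value, lod, loq)
    expect_equal(r2$reported_value, r1$reported_value)
    expect_gte(rank[r2$censor_status], rank[r1$censor_status])
    r3 <- censor_value(r2$reported_value, lod, loq)
    expect_equal(r3$reported_value, r2$reported_value)
  }
})

test_that("quantify_pool chains quantify -> blank-subtract -> censor", {
  # matrix response for true 0.1 with blank 0.02 at recovery 0.8
  slope_solvent <- 2.0
  mk <- function(total) {
    s <- addition_line(slope_solvent * 0.8, 0)
    s$response_ratio <- slope_solvent * 0.8 * (s$spike_level + total)
    s
  }
  res <- quantify_pool(mk(0.12), blank_series = mk(0.02),
                       lod_extract = 0.01, loq_extract = 0.025,
                       slope_solvent = slope_solvent)
  expect_equal(res$raw_estimate, 0.12, tolerance = 1e-12)
  expect_equal(res$blank_estimate, 0.02, tolerance = 1e-12)
  expect_equal(res$corrected, 0.10, tolerance = 1e-12)
  expect_equal(res$censor_status, "quantified")
  expect_equal(res$reported_value, 0.10, tolerance = 1e-12)
  expect_equal(res$recovery_percent, 80, tolerance = 1e-12)

  # a corrected value inside (LOD, LOQ) comes out as LOQ/2
  res2 <- quantify_pool(mk(0.015), lod_extract = 0.01, loq_extract = 0.025)
  expect_equal(res2$censor_status, "below_loq")
  expect_equal(res2$reported_value, 0.0125)
})

test_that("parameter recovery at 5% CV: median error under 10% of truth", {
  # truths at least twice the sample-unit LOQ
  cases <- data.frame(analyte = c("DEP", "DBP", "DEHP"),
                      slope = c(1.8091, 2.6487, 1.0437),
                      truth = c(0.329, 0.0370, 0.524),
                      recovery = c(0.98, 1.00, 0.93))
  for (k in seq_len(nrow(cases))) {
    rel_err <- vapply(1:200, function(s) {
      ser <- generate_addition_series(cases$analyte[k], "p",
                                      slope = cases$slope[k],
                                      recovery = cases$recovery[k],
                                      true_concentration = cases$truth[k],
                                      cv = 0.05, seed = 9000 + s)
      est <- native_concentration(fit_addition(ser))
      abs(est - cases$truth[k]) / cases$truth[k]
    }, numeric(1))
    expect_lt(stats::median(rel_err), 0.10)
  }
})

test_that("apply_censoring substitutes LOQ/2 for the censored phthalate", {
  cc <- apply_censoring(default_concentrations())
  dnop <- cc[cc$analyte == "DNOP", ]
  expect_equal(dnop$reported_value, rep(0.0125, 3))
  quant <- cc[cc$censor_status == "quantified", ]
  expect_equal(quant$reported_value, quant$corrected)
})
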