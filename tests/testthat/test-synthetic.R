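test_that("noiseless calibration generation evaluates the sensitivity line", {
  s <- generate_calibration_series("BHT", slope = 1.3579,
                                   intercept = -0.0011,
                                   levels = c(0, 1), cv = 0,
                                   replicates = 1, seed = 1)
  expect_equal(s$response_ratio, c(-0.0011, 1.3568))
  expect_error(generate_calibration_series("x", 1, 0, levels = c(-1, 1)),
               class = "fcm_domain_error")
})

test_that("generation is reproducible for a fixed seed", {
  a <- generate_calibration_series("DEP", 1.8, -0.02, c(0.01, 0.1, 1),
                                   cv = 0.05, seed = 99)
  b <- generate_calibration_series("DEP", 1.8, -0.02, c(0.01, 0.1, 1),
                                   cv = 0.05, seed = 99)
  expect_identical(a, b)
  c <- generate_calibration_series("DEP", 1.8, -0.02, c(0.01, 0.1, 1),
                                   cv = 0.05, seed = 100)
  expect_false(identical(b$response_ratio, c$response_ratio))
  # design columns do not depend on the seed
  expect_identical(b[c("analyte", "concentration", "replicate")],
                   c[c("analyte", "concentration", "replicate")])
})

test_that("the multiplicative noise model has the configured CV", {
  s <- generate_calibration_series("x", slope = 1, intercept = 0,
                                   levels = 1, cv = 0.05,
                                   replicates = 1000, seed = 5)
  cv_hat <- stats::sd(s$response_ratio) / mean(s$response_ratio)
  expect_lt(abs(cv_hat - 0.05) / 0.05, 0.2)
})

test_that("addition series uses the spike design verbatim and recovers truth", {
  s <- generate_addition_series("DEP", "1-2", slope = 2.0, recovery = 0.9,
                                true_concentration = 0.2, cv = 0,
                                unspiked_replicates = 1, seed = 1)
  expect_equal(sort(unique(s$spike_level)), c(0, 0.05, 0.1, 0.25, 0.5))
  f <- fit_addition(s)
  expect_equal(f$slope, 1.8, tolerance = 1e-12)  # sensitivity x recovery
  expect_equal(native_concentration(f), 0.2, tolerance = 1e-12)
  expect_error(generate_addition_series("x", "p", 1, 1, 0.1,
                                        spike_levels = c(0.05, 0.1)),
               class = "fcm_domain_error")
})

test_that("shared blank contamination is removed by blank subtraction", {
  mk <- function(true, blank, seed)
    generate_addition_series("x", "p", slope = 1.5, recovery = 0.8,
                             true_concentration = true,
                             blank_concentration = blank, cv = 0,
                             unspiked_replicates = 2, seed = seed)
  sample_series <- mk(0, 0.05, 1)
  blank_series <- mk(0, 0.05, 2)
  raw <- native_concentration(fit_addition(sample_series))
  bl <- native_concentration(fit_addition(blank_series))
  expect_equal(raw, 0.05, tolerance = 1e-12)
  expect_equal(blank_subtract(raw, bl), 0, tolerance = 1e-12)
})

test_that("a full bundle has one series per analyte x pool and is seed-stable", {
  cfg <- synthetic_config()
  b <- generate_study(cfg, seed = 7)
  expect_equal(nrow(unique(b$additions[c("analyte", "pool_id")])), 24)
  expect_equal(nrow(unique(b$blanks[c("analyte", "pool_id")])), 24)
  expect_equal(length(unique(b$calibration$analyte)), 8)
  b2 <- generate_study(cfg, seed = 7)
  expect_identical(b, b2)
  b3 <- generate_study(cfg, seed = 8)
  expect_identical(b$additions[c("analyte", "pool_id", "spike_level")],
                   b3$additions[c("analyte", "pool_id", "spike_level")])
  expect_false(identical(b$additions$response_ratio,
                         b3$additions$response_ratio))
})

test_that("noiseless bundles pass the full pipeline returning exact truth", {
  cfg <- synthetic_config(cv_repeatability = 0)
  b <- generate_study(cfg, seed = 3)
  q <- suppressWarnings(quantify_study(b$additions, b$blanks))
  m <- merge(q, cfg$truth, by = c("analyte", "age_group"))
  expect_equal(m$corrected, m$true_concentration, tolerance = 1e-9)
  expect_equal(m$recovery_percent, 100 * m$recovery_fraction,
               tolerance = 1e-9)
  # the below-LOQ DNOP truth is flagged as censored, everything else not
  expect_true(all(m$censor_status[m$analyte == "DNOP"] == "below_loq"))
  expect_true(all(m$censor_status[m$analyte != "DNOP"] == "quantified"))
})

test_that("estimator RMSE shrinks as unspiked replication grows", {
  rmse_at <- function(reps) {
    errs <- vapply(1:150, function(s) {
      ser <- generate_addition_series("DEP", "p", slope = 1.8091,
                                      recovery = 0.98,
                                      true_concentration = 0.329,
                                      cv = 0.05, unspiked_replicates = reps,
                                      seed = 5000 + s)
      native_concentration(fit_addition(ser)) - 0.329
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  r <- c(rmse_at(1), rmse_at(4), rmse_at(16))
  # monotone within Monte-Carlo slack
  expect_lt(r[2], r[1] * 1.1)
  expect_lt(r[3], r[2] * 1.1)
  expect_lt(r[3], r[1])
})

test_that("bundle files written to disk are byte-stable under a fixed seed", {
  cfg <- synthetic_config()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(cfg, seed = 11, dir = d1)
  simulate_study(cfg, seed = 11, dir = d2)
  for (f in c("calibration.csv", "additions.csv", "blanks.csv",
              "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  tr <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_equal(tr$seed, 11)
  expect_equal(length(tr$truth), 24)
})
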