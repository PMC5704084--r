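mk_readings <- function(sbp, dbp, elapsed = seq_along(sbp) * 10 - 10) {
  data.frame(subject_id = "s1", condition = "CONTROL", phase = "ambulatory",
             elapsed_min = elapsed, sbp = sbp, dbp = dbp, awake = TRUE)
}

test_that("QC bounds are strict: boundary readings retained, beyond rejected", {
  r <- mk_readings(sbp = c(221, 220, 80, 79, 150, 150, 150),
                   dbp = c(80, 80, 40, 80, 39, 131, 130))
  out <- qc_filter(r)
  expect_equal(out$retained$sbp, c(220, 80, 150))
  expect_equal(out$retained$dbp, c(80, 40, 130))
  expect_equal(nrow(out$rejected), 4)
  # partition is exhaustive and idempotent
  expect_equal(nrow(out$retained) + nrow(out$rejected), nrow(r))
  again <- qc_filter(out$retained)
  expect_equal(again$retained, out$retained)
  expect_equal(nrow(again$rejected), 0)
})

test_that("compliance arithmetic follows the 3-awake/2-sleep schedule and 80% rule", {
  c1 <- compliance_check(43, awake_hours = 16)
  expect_equal(c1$n_potential, 54)
  expect_false(c1$acceptable)
  expect_equal(c1$fraction, 43 / 54, tolerance = 1e-12)
  expect_true(compliance_check(44, awake_hours = 16)$acceptable)
  c2 <- compliance_check(46, awake_hours = 19)
  expect_equal(c2$n_potential, 57)
  expect_equal(round(c2$fraction, 3), 0.807)
  expect_true(c2$acceptable)
  full <- compliance_check(54, awake_hours = 16)
  expect_equal(full$fraction, 1.0)
  expect_true(full$acceptable)
  expect_error(compliance_check(10, awake_hours = 20), "awake_hours")
})

test_that("hourly binning averages within half-open hour windows", {
  r <- mk_readings(sbp = c(120, 130, 140), dbp = c(70, 80, 90),
                   elapsed = c(10, 30, 50))
  h <- hourly_bin(r)
  expect_equal(h$sbp[1], 130)
  expect_equal(h$dbp[1], 80)
  expect_true(all(is.na(h$sbp[2:19])))
  # a reading at exactly 60 min belongs to hour 2
  r2 <- mk_readings(sbp = c(100, 200), dbp = c(60, 70), elapsed = c(59.9, 60))
  h2 <- hourly_bin(r2)
  expect_equal(h2$sbp[1], 100)
  expect_equal(h2$sbp[2], 200)
  # random schedule equals an independent group-by oracle
  set.seed(5)
  r3 <- mk_readings(sbp = runif(50, 100, 160), dbp = runif(50, 60, 95),
                    elapsed = runif(50, 0, 19 * 60))
  h3 <- hourly_bin(r3)
  oracle <- tapply(r3$sbp, floor(r3$elapsed_min / 60) + 1, mean)
  for (hr in as.integer(names(oracle))) {
    expect_equal(h3$sbp[hr], unname(oracle[as.character(hr)]), tolerance = 1e-12)
  }
  # binned values never leave the range of their window's readings
  for (hr in 1:19) {
    w <- r3[floor(r3$elapsed_min / 60) + 1 == hr, ]
    if (nrow(w) > 0) {
      expect_gte(h3$sbp[hr], min(w$sbp))
      expect_lte(h3$sbp[hr], max(w$sbp))
    }
  }
})

test_that("baseline averaging and error on empty baselines", {
  b <- data.frame(sbp = 131:140, dbp = rep(80, 10))
  expect_equal(baseline_mean(b), c(sbp = 135.5, dbp = 80))
  expect_error(baseline_mean(b[0, ]), "no baseline")
})

test_that("bp_response differences the two change-from-baseline series", {
  hrs <- data.frame(hour = 1:19, sbp = 120, dbp = 75)
  base <- c(sbp = 120, dbp = 75)
  r0 <- bp_response(hrs, base, hrs, base)
  expect_true(all(r0$sbp == 0) && all(r0$dbp == 0))
  # E_h = E_base + 2 and C_h = C_base - 1 gives +3 at every hour
  eh <- data.frame(hour = 1:19, sbp = 122, dbp = 77)
  ch <- data.frame(hour = 1:19, sbp = 119, dbp = 74)
  r3 <- bp_response(eh, base, ch, base)
  expect_true(all(r3$sbp == 3) && all(r3$dbp == 3))
  expect_equal(attr(r3, "mean_19h")[["sbp"]], 3)
  # antisymmetry: swapping exercise and control negates every hour
  set.seed(9)
  e2 <- data.frame(hour = 1:19, sbp = rnorm(19, 125), dbp = rnorm(19, 80))
  c2 <- data.frame(hour = 1:19, sbp = rnorm(19, 120), dbp = rnorm(19, 78))
  b_e <- c(sbp = 124, dbp = 79)
  b_c <- c(sbp = 121, dbp = 77)
  fwd <- bp_response(e2, b_e, c2, b_c)
  rev <- bp_response(c2, b_c, e2, b_e)
  expect_equal(fwd$sbp, -rev$sbp, tolerance = 1e-12)
  expect_equal(fwd$dbp, -rev$dbp, tolerance = 1e-12)
  # missing hours propagate
  e3 <- e2; e3$sbp[5] <- NA
  r5 <- bp_response(e3, b_e, c2, b_c)
  expect_true(is.na(r5$sbp[5]))
})

test_that("AASI equals one minus the DBP-on-SBP slope on exact linear data", {
  sbp <- seq(100, 160, by = 5)
  expect_equal(aasi(data.frame(sbp = sbp, dbp = sbp)), 0)
  expect_equal(suppressWarnings(aasi(data.frame(sbp = sbp, dbp = rep(80, length(sbp))))), 1)
  expect_equal(aasi(data.frame(sbp = sbp, dbp = 0.4 * sbp + 32)), 0.6,
               tolerance = 1e-12)
  expect_error(aasi(data.frame(sbp = rep(120, 5), dbp = 1:5)), "variance")
  expect_warning(aasi(data.frame(sbp = sbp, dbp = 2 * sbp)), "plausible")
})

test_that("a noiseless cohort with an injected shift yields exactly that response in carriers", {
  cfg <- cohort_config(
    n_subjects_per_stratum = c(AF = 8),
    variants = list(list(id = "v1", chrom = "7", pos = 100, ref = "A",
                         alt = "G", counts = list(AF = c(4, 4, 0)))),
    effect_map = list(list(variant = "v1", sbp = -10, dbp = -4)),
    covariate_params = table_covariate_params()["AF"],
    rho = 0, sigma_hour = 0, sigma_reading = 0, subject_sd = 0,
    missing_rate = 0, outlier_rate = 0, seed = 7)
  co <- simulate_cohort(cfg)
  ph <- compute_responses(co$readings)
  dos <- co$genotypes$dosages[, "v1"]
  for (sid in names(dos)) {
    sbp <- ph$responses[ph$responses$subject_id == sid &
                          ph$responses$phenotype == "SBP" &
                          ph$responses$intensity == "VIGOROUS", "response"]
    expect_equal(sbp, rep(-10 * dos[[sid]], 19), tolerance = 1e-10)
  }
  # zero-effect, zero-noise null: everything identically zero
  cfg0 <- cohort_config(
    n_subjects_per_stratum = c(AF = 6),
    variants = list(list(id = "v1", chrom = "7", pos = 100, ref = "A",
                         alt = "G", counts = list(AF = c(3, 3, 0)))),
    covariate_params = table_covariate_params()["AF"],
    rho = 0, sigma_hour = 0, sigma_reading = 0, subject_sd = 0,
    missing_rate = 0, outlier_rate = 0, seed = 8)
  ph0 <- compute_responses(simulate_cohort(cfg0)$readings)
  expect_true(all(abs(ph0$responses$response) < 1e-10))
})
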