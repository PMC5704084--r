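test_that("genotype draws follow Hardy-Weinberg proportions", {
  expect_equal(draw_genotypes(0, 10), rep(0L, 10))
  set.seed(23)
  g1 <- draw_genotypes(0.5, 1000)
  set.seed(23)
  g2 <- draw_genotypes(0.5, 1000)
  expect_identical(g1, g2)
  set.seed(29)
  g <- draw_genotypes(0.5, 100000)
  obs <- tabulate(g + 1, 3)
  gof <- chisq.test(obs, p = c(0.25, 0.5, 0.25))
  expect_gt(gof$p.value, 0.001)
  expect_error(draw_genotypes(0.6, 10), "maf")
})

test_that("HOMA-IR evaluates glucose x insulin / 405", {
  expect_equal(homa_ir(405, 1), 1.0)
  expect_equal(homa_ir(90, 9), 2.0)
  expect_equal(homa_ir(97.2, 9.4), 97.2 * 9.4 / 405, tolerance = 1e-12)
  # order of magnitude of a typical subject: ~2.3
  expect_lt(abs(homa_ir(97.2, 9.4) - 2.3), 1)
  expect_error(homa_ir(0, 5), "positive")
})

test_that("Friedewald LDL evaluates TC - HDL - TG/5 with the validity bound", {
  expect_equal(friedewald_ldl(200, 50, 100), 130)
  expect_equal(friedewald_ldl(60, 60, 0), 0)
  expect_equal(friedewald_ldl(178.5, 53.9, 83.7), 107.86, tolerance = 1e-10)
  expect_error(friedewald_ldl(200, 50, 400), "400")
})

test_that("simulated cohorts have the contracted structure", {
  cfg <- cohort_config(seed = 31)
  co <- simulate_cohort(cfg)
  r <- co$readings
  # every subject has all three conditions with baseline and ambulatory phases
  for (sid in names(co$strata)) {
    sub <- r[r$subject_id == sid, ]
    expect_setequal(unique(sub$condition), c("CONTROL", "MODERATE", "VIGOROUS"))
    expect_true(all(table(sub$condition, sub$phase)[, "baseline"] == 10))
  }
  expect_true(all(co$genotypes$dosages %in% c(0, 1, 2)))
  # fixed genotype counts are honoured exactly
  af <- names(co$strata)[co$strata == "AF"]
  expect_equal(as.integer(table(factor(co$genotypes$dosages[af, "rs891512"],
                                       levels = 0:2))), c(13L, 1L, 0L))
  # covariates carry the derived quantities
  expect_equal(co$covariates$homa,
               homa_ir(co$covariates$glucose, co$covariates$insulin))
  # determinism under the config seed
  co2 <- simulate_cohort(cfg)
  expect_identical(co$readings, co2$readings)
  expect_identical(co$genotypes$dosages, co2$genotypes$dosages)
})

test_that("outliers violate QC bounds at roughly the configured rate and missing thins readings", {
  cfg <- cohort_config(outlier_rate = 0.1, missing_rate = 0.2, seed = 37)
  co <- simulate_cohort(cfg)
  amb <- co$readings[co$readings$phase == "ambulatory", ]
  rej_rate <- nrow(qc_filter(amb)$rejected) / nrow(amb)
  expect_gt(rej_rate, 0.05)
  expect_lt(rej_rate, 0.15)
  full <- 23 * 3 * (3 * 16 + 2 * 3)
  expect_lt(nrow(amb), full * 0.9)
})

test_that("within-subject response noise has the configured lag-1 autocorrelation", {
  cfg <- cohort_config(
    n_subjects_per_stratum = c(AF = 400),
    variants = list(list(id = "v1", chrom = "7", pos = 1, ref = "A",
                         alt = "G", maf = 0.3)),
    covariate_params = table_covariate_params()["AF"],
    rho = 0.8, sigma_hour = 10, sigma_reading = 0, subject_sd = 5,
    missing_rate = 0, outlier_rate = 0, seed = 41)
  co <- simulate_cohort(cfg)
  lat <- co$latent[co$latent$phenotype == "SBP" &
                     co$latent$intensity == "VIGOROUS", ]
  # pool lagged pairs across subjects: per-series estimates at 19 points are
  # badly biased downward, pooled pairs are not
  by_subj <- split(lat$response, lat$subject_id)
  prev <- unlist(lapply(by_subj, function(x) x[-length(x)]))
  nxt <- unlist(lapply(by_subj, function(x) x[-1]))
  expect_lt(abs(cor(prev, nxt) - 0.8), 0.05)
})

test_that("cohort files round-trip: readings CSV and truth JSON", {
  cfg <- cohort_config(seed = 43)
  co <- simulate_cohort(cfg)
  dir <- file.path(tempdir(), "cohort_out")
  write_cohort(co, dir)
  r2 <- read.csv(file.path(dir, "readings.csv"))
  expect_equal(nrow(r2), nrow(co$readings))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(tr$rho, 0.6)
  unlink(dir, recursive = TRUE)
})

test_that("YAML configs build validated cohort configurations", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_subjects_per_stratum:", "  AF: 4", "  CAU: 3",
    "rho: 0.5", "sigma_hour: 6", "seed: 11",
    "variants:",
    "  - id: v1", "    chrom: '7'", "    pos: 10", "    ref: A",
    "    alt: G", "    maf: 0.25"), path)
  cfg <- read_cohort_config(path)
  expect_s3_class(cfg, "cohort_config")
  expect_equal(cfg$n_subjects_per_stratum, c(AF = 4, CAU = 3))
  expect_equal(cfg$rho, 0.5)
  co <- simulate_cohort(cfg)
  expect_equal(length(co$strata), 7)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(rho = 1), "rho")
  expect_error(cohort_config(sigma_hour = -1), "SD")
  expect_error(cohort_config(awake_hours = 25), "awake")
  expect_error(cohort_config(variants = list(
    list(id = "v", chrom = "7", pos = 1, ref = "A", alt = "G", maf = 0.7))),
    "maf")
  expect_error(cohort_config(variants = list(
    list(id = "v", chrom = "7", pos = 1, ref = "A", alt = "G",
         counts = list(AF = c(1, 1, 1))))),
    "sum")
})
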