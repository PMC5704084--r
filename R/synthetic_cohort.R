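#' Homeostasis model assessment of insulin resistance (HOMA-IR)
#'
#' `glucose * insulin / 405` with glucose in mg/dL and insulin in uU/mL
#' (the 405 constant is the mass-unit form of the index).
#'
#' @param glucose fasting glucose, mg/dL (positive).
#' @param insulin fasting insulin, uU/mL (positive).
#' @export
homa_ir <- function(glucose, insulin) {
  if (any(glucose <= 0) || any(insulin <= 0)) {
    stop("glucose and insulin must be positive")
  }
  glucose * insulin / 405
}

#' Friedewald estimate of LDL cholesterol
#'
#' `TC - HDL - TG/5` (mg/dL). The equation is invalid at triglycerides
#' >= 400 mg/dL, which is rejected.
#'
#' @param tc total cholesterol, mg/dL.
#' @param hdl HDL cholesterol, mg/dL.
#' @param tg triglycerides, mg/dL (< 400).
#' @export
friedewald_ldl <- function(tc, hdl, tg) {
  if (any(tg >= 400)) stop("Friedewald equation invalid at triglycerides >= 400 mg/dL")
  tc - hdl - tg / 5
}

#' Draw genotypes under Hardy-Weinberg equilibrium
#'
#' Minor-allele dosages sampled with probabilities `((1-q)^2, 2q(1-q), q^2)`
#' for minor-allele frequency `q`.
#'
#' @param maf minor-allele frequency in `[0, 0.5]`.
#' @param n number of subjects.
#' @export
draw_genotypes <- function(maf, n) {
  if (maf < 0 || maf > 0.5) stop("maf must be in [0, 0.5]")
  stopifnot(n >= 1)
  q <- maf
  sample(0:2, n, replace = TRUE, prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
}

#' Default synthetic variant panel
#'
#' A synthetic stand-in for a small exonic sequencing panel: biallelic
#' variants on chromosome 7 with per-stratum genotype counts chosen to mirror
#' published genotype-group sizes in a 14 + 9 two-stratum cohort (`counts`
#' entries give the number of subjects with 0, 1 and 2 minor alleles per
#' stratum). Positions and alleles are invented.
#'
#' @export
default_variant_panel <- function() {
  mk <- function(id, pos, ref, alt, af, cau) {
    list(id = id, chrom = "7", pos = pos, ref = ref, alt = alt,
         counts = list(AF = af, CAU = cau))
  }
  list(
    mk("rs891512",    151010650, "G", "A", c(13, 1, 0), c(3, 5, 1)),
    mk("rs867225",    151010700, "A", "C", c(9, 5, 0),  c(9, 0, 0)),
    mk("rs743507",    151010750, "A", "G", c(9, 5, 0),  c(3, 5, 1)),
    mk("rs41483644",  151010800, "C", "T", c(13, 1, 0), c(9, 0, 0)),
    mk("rs3730009",   151010850, "C", "T", c(7, 6, 1),  c(9, 0, 0)),
    mk("rs77325852",  151010900, "G", "A", c(8, 5, 1),  c(9, 0, 0)),
    mk("rs3918164",   151010950, "G", "A", c(12, 2, 0), c(9, 0, 0))
  )
}

#' Default covariate distribution parameters
#'
#' Per-stratum means and SDs of the subject characteristics the analysis
#' uses, taken from the study-population description of a hypertensive,
#' overweight two-ethnicity cohort (African American stratum `AF`, Caucasian
#' stratum `CAU`). Skewed positive covariates (AASI, insulin, triglycerides,
#' endothelin) are simulated log-normally with moments matched to these
#' values; the rest are normal.
#'
#' @export
table_covariate_params <- function() {
  list(
    AF = list(
      age = c(39.9, 10.6), bmi = c(31.1, 4.5), orient_sbp = c(140.2, 12.3),
      orient_dbp = c(84.3, 6.9), glucose = c(97.2, 10.3), aasi = c(0.391, 0.143),
      insulin = c(9.4, 6.0), tc = c(178.5, 27.3), hdl = c(53.9, 14.8),
      tg = c(83.7, 35.8), endothelin = c(0.378, 0.663), p_female = 0.3
    ),
    CAU = list(
      age = c(45.1, 7.8), bmi = c(30.5, 1.8), orient_sbp = c(139.3, 7.0),
      orient_dbp = c(85.0, 5.1), glucose = c(96.4, 12.2), aasi = c(0.415, 0.093),
      insulin = c(13.1, 10.1), tc = c(207.8, 31.3), hdl = c(44.1, 10.9),
      tg = c(170.8, 88.8), endothelin = c(0.222, 0.213), p_female = 0.3
    )
  )
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_subjects_per_stratum named integer vector, stratum label to
#'   subject count.
#' @param variants list of variant descriptors: `id`, `chrom`, `pos`, `ref`,
#'   `alt`, and either `maf` (Hardy-Weinberg draw) or `counts` (named list,
#'   stratum to exact genotype counts `c(n0, n1, n2)`).
#' @param effect_map list of genetic effects on the hourly response: each
#'   entry has `variant`, per-minor-allele shifts `sbp` and `dbp` (mmHg),
#'   optional cubic time-modulation coefficients `sbp_time`/`dbp_time`
#'   (length 3, multiplying `t, t^2, t^3`), and `intensity` (conditions the
#'   effect applies to; default both).
#' @param covariate_params per-stratum covariate means/SDs; see
#'   [table_covariate_params()].
#' @param covariate_effects optional named list, covariate name to
#'   `c(sbp = , dbp = )` slopes on the hourly response.
#' @param rho AR(1) correlation of the hourly response noise, `|rho| < 1`.
#' @param sigma_hour SD (mmHg) of the hourly response noise (the AR(1)
#'   innovation scale of the differenced phenotype).
#' @param sigma_reading SD (mmHg) of reading-level measurement noise.
#' @param subject_sd SD (mmHg) of a subject-level BP shift shared across
#'   conditions; it cancels in the exercise-minus-control difference, which
#'   is the rationale for the differenced phenotype.
#' @param awake_hours waking hours out of 19 (3 readings per awake hour, 2
#'   per sleep hour).
#' @param missing_rate fraction of ambulatory readings dropped at random.
#' @param outlier_rate fraction of ambulatory readings pushed outside the
#'   device QC bounds.
#' @param geno_missing_rate fraction of genotype calls set to missing.
#' @param seed integer seed making the cohort reproducible.
#' @return validated config list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects_per_stratum = c(AF = 14, CAU = 9),
                          variants = default_variant_panel(),
                          effect_map = list(),
                          covariate_params = table_covariate_params(),
                          covariate_effects = NULL,
                          rho = 0.6, sigma_hour = 10, sigma_reading = 8,
                          subject_sd = 8, awake_hours = 16,
                          missing_rate = 0.05, outlier_rate = 0.02,
                          geno_missing_rate = 0, seed = 1) {
  stopifnot(length(n_subjects_per_stratum) >= 1,
            !is.null(names(n_subjects_per_stratum)),
            all(n_subjects_per_stratum >= 1))
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (sigma_hour < 0 || sigma_reading < 0 || subject_sd < 0) {
    stop("all SDs must be >= 0")
  }
  if (awake_hours < 0 || awake_hours > 19) stop("awake_hours must be in 0..19")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (outlier_rate < 0 || outlier_rate >= 1) stop("outlier_rate must be in [0, 1)")
  for (v in variants) {
    if (is.null(v$counts)) {
      if (is.null(v$maf) || v$maf < 0 || v$maf > 0.5) {
        stop("variant ", v$id, ": maf must be in [0, 0.5] (or give counts)")
      }
    } else {
      bad <- setdiff(names(v$counts), names(n_subjects_per_stratum))
      if (length(bad) > 0) stop("variant ", v$id, ": unknown stratum ", bad[1])
      for (st in names(v$counts)) {
        if (sum(v$counts[[st]]) != n_subjects_per_stratum[[st]]) {
          stop("variant ", v$id, ": counts for ", st, " must sum to ",
               n_subjects_per_stratum[[st]])
        }
      }
    }
  }
  structure(list(
    n_subjects_per_stratum = n_subjects_per_stratum, variants = variants,
    effect_map = effect_map, covariate_params = covariate_params,
    covariate_effects = covariate_effects, rho = rho, sigma_hour = sigma_hour,
    sigma_reading = sigma_reading, subject_sd = subject_sd,
    awake_hours = awake_hours, missing_rate = missing_rate,
    outlier_rate = outlier_rate, geno_missing_rate = geno_missing_rate,
    seed = seed), class = "cohort_config")
}

# stationary AR(1) series with marginal SD `sd`
ar1_series <- function(n, rho, sd) {
  if (sd == 0) return(numeric(n))
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - rho^2))
    for (t in 2:n) e[t] <- rho * e[t - 1] + innov[t - 1]
  }
  e
}

# log-normal draw matching a target mean and SD
rlnorm_ms <- function(n, m, s) {
  if (s == 0) return(rep(m, n))
  sigma2 <- log(1 + (s / m)^2)
  stats::rlnorm(n, meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Simulate a complete synthetic study cohort
#'
#' Generates reading-level ambulatory BP data for CONTROL, MODERATE and
#' VIGOROUS conditions (plus 20-min pre-experiment baselines), genotypes,
#' and a covariate table, with the statistical structure the downstream
#' analysis assumes. The latent hourly response of subject i at hour t is
#' the sum of configured genetic effects (`dosage * effect(t)`), covariate
#' effects, and AR(1) noise with parameters `rho`/`sigma_hour`; a shared
#' subject-level shift enters every condition and so cancels in the
#' differenced phenotype. Reading-level records are emitted at 3 per awake
#' hour and 2 per sleep hour with additional measurement noise; a fraction
#' `outlier_rate` violate the device QC bounds and a fraction `missing_rate`
#' are dropped.
#'
#' @param config a [cohort_config()].
#' @return list of class `"synthetic_cohort"`: `readings`, `genotypes`
#'   (`dosages` matrix plus `info`), `covariates`, `strata` (named vector),
#'   `latent` (the noiseless-measurement hourly responses), and `truth`
#'   (the generating parameters, for recovery tests).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  strata_labels <- names(config$n_subjects_per_stratum)
  subjects <- unlist(lapply(strata_labels, function(st) {
    sprintf("%s%02d", st, seq_len(config$n_subjects_per_stratum[[st]]))
  }))
  strata <- unlist(lapply(strata_labels, function(st) {
    rep(st, config$n_subjects_per_stratum[[st]])
  }))
  names(strata) <- subjects
  n <- length(subjects)

  ## covariates
  cov_rows <- lapply(seq_len(n), function(i) {
    pars <- config$covariate_params[[strata[i]]]
    if (is.null(pars)) stop("no covariate_params for stratum ", strata[i])
    g <- function(nm) stats::rnorm(1, pars[[nm]][1], pars[[nm]][2])
    gl <- function(nm) rlnorm_ms(1, pars[[nm]][1], pars[[nm]][2])
    glucose <- max(g("glucose"), 40)
    insulin <- gl("insulin")
    tc <- max(g("tc"), 80)
    hdl <- max(g("hdl"), 15)
    tg <- min(gl("tg"), 399)
    data.frame(
      subject_id = subjects[i], stratum = strata[i],
      age = g("age"), bmi = g("bmi"),
      gender = stats::rbinom(1, 1, pars$p_female),
      aasi = gl("aasi"), orient_sbp = g("orient_sbp"),
      glucose = glucose, insulin = insulin,
      homa = homa_ir(glucose, insulin),
      tc = tc, hdl = hdl, tg = tg,
      ldl = friedewald_ldl(tc, hdl, tg),
      endothelin = gl("endothelin"))
  })
  covariates <- do.call(rbind, cov_rows)

  ## genotypes
  geno_cols <- list()
  info_rows <- list()
  for (v in config$variants) {
    if (!is.null(v$counts)) {
      dos <- numeric(n)
      for (st in strata_labels) {
        ids <- which(strata == st)
        cnt <- v$counts[[st]]
        if (is.null(cnt)) {
          dos[ids] <- 0
        } else {
          pool <- rep(0:2, times = cnt)
          dos[ids] <- pool[sample.int(length(pool))]
        }
      }
    } else {
      dos <- draw_genotypes(v$maf, n)
    }
    if (config$geno_missing_rate > 0) {
      dos[stats::runif(n) < config$geno_missing_rate] <- NA
    }
    geno_cols[[v$id]] <- dos
    info_rows[[v$id]] <- data.frame(variant_id = v$id, chrom = v$chrom,
                                    pos = v$pos, ref = v$ref, alt = v$alt)
  }
  dosages <- do.call(cbind, geno_cols)
  rownames(dosages) <- subjects

  ## genetic effect on the hourly response, per subject/hour/phenotype/intensity
  hours <- 1:19
  effect_profile <- function(sid, phen, intensity) {
    tot <- numeric(length(hours))
    for (e in config$effect_map) {
      ints <- if (is.null(e$intensity)) c("MODERATE", "VIGOROUS") else e$intensity
      if (!intensity %in% ints) next
      d <- dosages[sid, e$variant]
      if (is.na(d) || d == 0) next
      base <- if (is.null(e[[phen]])) 0 else e[[phen]]
      tm <- e[[paste0(phen, "_time")]]
      prof <- base + if (is.null(tm)) 0 else tm[1] * hours + tm[2] * hours^2 + tm[3] * hours^3
      tot <- tot + d * prof
    }
    if (!is.null(config$covariate_effects)) {
      for (cv in names(config$covariate_effects)) {
        sl <- config$covariate_effects[[cv]][[phen]]
        if (!is.null(sl)) {
          x <- covariates[covariates$subject_id == sid, cv]
          tot <- tot + sl * x
        }
      }
    }
    tot
  }

  awake <- c(rep(TRUE, config$awake_hours), rep(FALSE, 19 - config$awake_hours))
  circadian <- ifelse(awake, 0, -8) + 2 * sin(2 * pi * hours / 19)
  offsets <- list(awake = c(10, 30, 50), sleep = c(15, 45))
  conditions <- c("CONTROL", "MODERATE", "VIGOROUS")
  amb_off <- unlist(lapply(hours, function(h) {
    60 * (h - 1) + (if (awake[h]) offsets$awake else offsets$sleep)
  }))
  amb_hour_idx <- rep(hours, times = ifelse(awake, 3, 2))
  n_amb <- length(amb_off)
  nb <- 10L  # baseline: one reading every 2 min for 20 min

  reading_rows <- list()
  latent_rows <- list()
  for (i in seq_len(n)) {
    sid <- subjects[i]
    pars <- config$covariate_params[[strata[i]]]
    base_sbp <- stats::rnorm(1, pars$orient_sbp[1], pars$orient_sbp[2] / 2)
    base_dbp <- stats::rnorm(1, pars$orient_dbp[1], pars$orient_dbp[2] / 2)
    subj_sbp <- stats::rnorm(1, 0, config$subject_sd)
    subj_dbp <- stats::rnorm(1, 0, config$subject_sd * 0.6)

    # split the hourly response noise between conditions so the differenced
    # phenotype has AR(1) noise with SD sigma_hour
    noise <- list()
    for (cond in conditions) {
      noise[[cond]] <- list(
        sbp = ar1_series(19, config$rho, config$sigma_hour / sqrt(2)),
        dbp = ar1_series(19, config$rho, config$sigma_hour / sqrt(2)))
    }

    for (cond in conditions) {
      eff_sbp <- if (cond == "CONTROL") numeric(19) else effect_profile(sid, "sbp", cond)
      eff_dbp <- if (cond == "CONTROL") numeric(19) else effect_profile(sid, "dbp", cond)
      hr_sbp <- base_sbp + subj_sbp + circadian + eff_sbp + noise[[cond]]$sbp
      hr_dbp <- base_dbp + subj_dbp + circadian * 0.5 + eff_dbp + noise[[cond]]$dbp

      if (cond != "CONTROL") {
        latent_rows[[length(latent_rows) + 1L]] <- data.frame(
          subject_id = sid, intensity = cond,
          phenotype = rep(c("SBP", "DBP"), each = 19),
          hour = rep(hours, 2),
          response = c(eff_sbp + noise[[cond]]$sbp - noise$CONTROL$sbp,
                       eff_dbp + noise[[cond]]$dbp - noise$CONTROL$dbp))
      }

      reading_rows[[length(reading_rows) + 1L]] <- data.frame(
        subject_id = sid, condition = cond,
        phase = c(rep("baseline", nb), rep("ambulatory", n_amb)),
        elapsed_min = c(seq(0, by = 2, length.out = nb), amb_off),
        sbp = c(base_sbp + subj_sbp + stats::rnorm(nb, 0, config$sigma_reading),
                hr_sbp[amb_hour_idx] + stats::rnorm(n_amb, 0, config$sigma_reading)),
        dbp = c(base_dbp + subj_dbp + stats::rnorm(nb, 0, config$sigma_reading),
                hr_dbp[amb_hour_idx] + stats::rnorm(n_amb, 0, config$sigma_reading)),
        awake = c(rep(TRUE, nb), awake[amb_hour_idx]))
    }
  }
  readings <- do.call(rbind, reading_rows)
  rownames(readings) <- NULL

  amb <- which(readings$phase == "ambulatory")
  if (config$outlier_rate > 0) {
    out_idx <- amb[stats::runif(length(amb)) < config$outlier_rate]
    for (j in out_idx) {
      type <- sample(4, 1)
      if (type == 1) readings$sbp[j] <- stats::runif(1, 225, 260)
      if (type == 2) readings$sbp[j] <- stats::runif(1, 50, 75)
      if (type == 3) readings$dbp[j] <- stats::runif(1, 132, 150)
      if (type == 4) readings$dbp[j] <- stats::runif(1, 25, 38)
    }
  }
  if (config$missing_rate > 0) {
    amb <- which(readings$phase == "ambulatory")
    drop <- amb[stats::runif(length(amb)) < config$missing_rate]
    if (length(drop) > 0) readings <- readings[-drop, , drop = FALSE]
  }

  latent <- do.call(rbind, latent_rows)
  rownames(latent) <- NULL

  structure(list(
    readings = readings,
    genotypes = list(dosages = dosages, info = do.call(rbind, c(info_rows, make.row.names = FALSE))),
    covariates = covariates,
    strata = strata,
    latent = latent,
    truth = list(effect_map = config$effect_map, rho = config$rho,
                 sigma_hour = config$sigma_hour,
                 sigma_reading = config$sigma_reading,
                 subject_sd = config$subject_sd, seed = config$seed)
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$strata), "subjects (",
      paste(names(table(x$strata)), table(x$strata), collapse = ", "), "),",
      ncol(x$genotypes$dosages), "variants,", nrow(x$readings), "readings\n")
  invisible(x)
}

#' Write a VCF v4.2 for a dosage matrix
#'
#' Emits biallelic sites with a GT field; dosage 0/1/2 becomes `0/0`, `0/1`,
#' `1/1` and missing becomes `./.`.
#'
#' @param dosages subjects x variants dosage matrix.
#' @param info variant metadata (`variant_id`, `chrom`, `pos`, `ref`, `alt`).
#' @param path output path.
#' @export
write_vcf <- function(dosages, info, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pehgene",
    '##FILTER=<ID=PASS,Description="All filters passed">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dosages)), collapse = "\t"))
  body <- vapply(seq_len(nrow(info)), function(i) {
    d <- dosages[, info$variant_id[i]]
    gts <- ifelse(is.na(d), "./.", gt_code[d + 1])
    paste(c(info$chrom[i], info$pos[i], info$variant_id[i], info$ref[i],
            info$alt[i], ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the synthetic cohort to a directory
#'
#' Readings and covariates as CSV, genotypes as VCF v4.2, generating truth
#' as JSON.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$readings, file.path(dir, "readings.csv"), row.names = FALSE)
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"), row.names = FALSE)
  write_vcf(cohort$genotypes$dosages, cohort$genotypes$info,
            file.path(dir, "cohort.vcf"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(cohort_config)))]
  if (!is.null(args$n_subjects_per_stratum)) {
    args$n_subjects_per_stratum <- unlist(args$n_subjects_per_stratum)
  }
  do.call(cohort_config, args)
}
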