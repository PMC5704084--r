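#' Run the full screening pipeline
#'
#' Orchestrates simulate (optional) -> phenotype -> genotypes -> screen ->
#' finalize -> power as one reproducible run. Inputs are either paths to a
#' readings CSV, a VCF and a covariates CSV, or a `simulate` block (a
#' [cohort_config()]); with a simulate block the synthetic files are written
#' and then read back through the same ingestion code paths as real data.
#' One base seed fans out to per-stage seeds (`seed + 1` for simulation,
#' `seed + 6` for power), so stages are independently rerunnable.
#'
#' @param config list with elements: either `simulate` (a `cohort_config`)
#'   or `readings`/`vcf`/`covariates` paths plus `strata` (named vector
#'   subject -> stratum); optional `phenotypes`, `intensities`,
#'   `thresholds` (`bonferroni`, `by`), `test` (`"LRT"`/`"WaldF"`),
#'   `candidates`, `log_covariates`, `power` (list: `enabled`, `n_sims`),
#'   `seed`.
#' @param out_dir output directory.
#' @return list of class `"pipeline_run"` with the screen table, hits,
#'   final models, power table and manifest; all tables are also written
#'   under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(is.list(config))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  phenotypes <- config$phenotypes %||% c("SBP", "DBP")
  intensities <- config$intensities %||% c("MODERATE", "VIGOROUS")
  thresholds <- config$thresholds %||% list(bonferroni = 0.05, by = 0.25)
  test <- config$test %||% "LRT"
  candidates <- config$candidates %||% c("age", "gender", "bmi", "aasi",
                                         "orient_sbp", "tg", "endothelin",
                                         "insulin")
  log_covariates <- config$log_covariates %||% c("aasi", "tg", "endothelin",
                                                 "insulin")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ## stage 1: inputs
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- seed + 1L
    cohort <- simulate_cohort(sim_cfg)
    data_dir <- file.path(out_dir, "data")
    write_cohort(cohort, data_dir)
    readings_path <- file.path(data_dir, "readings.csv")
    vcf_path <- file.path(data_dir, "cohort.vcf")
    covariates_path <- file.path(data_dir, "covariates.csv")
    strata <- cohort$strata
  } else {
    readings_path <- config$readings
    vcf_path <- config$vcf
    covariates_path <- config$covariates
    strata <- config$strata
    if (is.null(readings_path) || is.null(vcf_path) ||
        is.null(covariates_path) || is.null(strata)) {
      stop("config needs either a 'simulate' block or readings/vcf/covariates paths plus strata")
    }
  }
  readings <- utils::read.csv(readings_path)
  covariates <- utils::read.csv(covariates_path)
  utils::write.csv(data.frame(subject_id = names(strata),
                              stratum = unname(strata)),
                   file.path(out_dir, "strata.csv"), row.names = FALSE)

  ## stage 2: phenotype
  phen <- compute_responses(readings, intensities = intensities)
  utils::write.csv(phen$responses, file.path(out_dir, "responses.csv"),
                   row.names = FALSE)
  utils::write.csv(phen$mean_19h, file.path(out_dir, "mean_19h.csv"),
                   row.names = FALSE)

  ## stage 3: genotypes
  gm <- genotype_matrix(vcf_path, names(strata), strata = strata)
  utils::write.csv(data.frame(subject_id = rownames(gm$dosages), gm$dosages,
                              check.names = FALSE),
                   file.path(out_dir, "dosages.csv"), row.names = FALSE)

  ## stage 4: screen
  screen <- screen_variants(phen$responses, phen$mean_19h, gm$dosages, strata,
                            phenotypes = phenotypes,
                            intensities = intensities, test = test)
  utils::write.table(screen, file.path(out_dir, "screen.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  hits <- select_hits(screen, thresholds$bonferroni, thresholds$by)
  utils::write.table(hits, file.path(out_dir, "hits.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  ## stage 5: final models per hit
  finals <- list()
  if (nrow(hits) > 0) {
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      subjects <- names(strata)[strata == h$stratum]
      rows <- phen$responses[phen$responses$phenotype == h$phenotype &
                               phen$responses$intensity == h$intensity &
                               phen$responses$subject_id %in% subjects, ]
      dosage <- gm$dosages[subjects, h$variant_id]
      fm <- tryCatch(
        select_model(rows, dosage, covariates[covariates$subject_id %in% subjects, ],
                     candidates = candidates, log_covariates = log_covariates,
                     variant_id = h$variant_id),
        error = function(e) NULL)
      if (!is.null(fm)) {
        key <- paste(h$variant_id, h$phenotype, h$intensity, h$stratum, sep = "_")
        finals[[key]] <- fm
      }
    }
  }
  jsonlite::write_json(
    lapply(finals, function(f) {
      list(variant_id = f$variant_id, terms = f$terms, coding = f$coding,
           correlation = f$correlation, reml_beta = as.list(f$reml_beta),
           pve_covariates_only = f$pve_covariates_only,
           partial_pve_snp = f$partial_pve_snp, lrt_p_snp = f$lrt_p_snp,
           n_subjects = f$n_subjects)
    }),
    file.path(out_dir, "final_models.json"), auto_unbox = TRUE, digits = NA)

  ## stage 6: power per hit (optional)
  power_tab <- NULL
  if (isTRUE(config$power$enabled) && nrow(hits) > 0) {
    n_sims <- config$power$n_sims %||% 1000
    rows_list <- list()
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      subjects <- names(strata)[strata == h$stratum]
      rows <- phen$responses[phen$responses$phenotype == h$phenotype &
                               phen$responses$intensity == h$intensity &
                               phen$responses$subject_id %in% subjects, ]
      dosage <- gm$dosages[subjects, h$variant_id]
      sc <- screen_one(dosage, rows, test = "WaldF")
      if (isTRUE(sc$skipped)) next
      beta <- sc$fit$beta
      names(beta)[names(beta) == "(Intercept)"] <- "intercept"
      obs <- table(factor(dosage[!is.na(dosage)], levels = 0:2))
      spec <- power_spec(n_subjects = length(subjects),
                         geno_probs = as.numeric(obs) / sum(obs),
                         beta = beta, rho = sc$fit$rho,
                         sigma2 = sc$fit$sigma2, n_sims = n_sims,
                         alpha = 0.05 / h$m)
      pr <- estimate_power(spec, seed = seed + 6L + i)
      rows_list[[i]] <- data.frame(
        variant_id = h$variant_id, phenotype = h$phenotype,
        intensity = h$intensity, stratum = h$stratum,
        power = pr$power, mc_se = pr$mc_se, n_converged = pr$n_converged,
        alpha = spec$alpha)
    }
    power_tab <- do.call(rbind, rows_list)
    if (!is.null(power_tab)) {
      utils::write.table(power_tab, file.path(out_dir, "power.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }

  ## manifest
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "simulate")],
                               auto_unbox = TRUE, force = TRUE)
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pehgene")),
    r_version = R.version.string,
    seed = seed,
    stage_seeds = list(simulate = seed + 1L, power_base = seed + 6L),
    config_hash = unname(tools::md5sum(tmp)),
    n_screen_records = nrow(screen), n_hits = nrow(hits))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(list(screen = screen, hits = hits, finals = finals,
                 power = power_tab, manifest = manifest, out_dir = out_dir),
            class = "pipeline_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble report tables from a completed run
#'
#' Builds a genotype-group summary table (per hit: #MA group sizes, means
#' and SDs of the 19-h-averaged response) and a final-model table (terms,
#' REML estimates, PVE, partial PVE, LRT p) from a run directory.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return list with `group_table` and `model_table` data frames (empty with
#'   zero hits).
#' @export
render_report <- function(run_dir) {
  hits_path <- file.path(run_dir, "hits.tsv")
  if (!file.exists(hits_path)) stop("incomplete run: ", hits_path, " missing")
  hits <- utils::read.delim(hits_path)
  mean19 <- utils::read.csv(file.path(run_dir, "mean_19h.csv"))
  dosages_df <- utils::read.csv(file.path(run_dir, "dosages.csv"),
                                check.names = FALSE)
  dosages <- as.matrix(dosages_df[, -1, drop = FALSE])
  rownames(dosages) <- dosages_df$subject_id
  strata_df <- utils::read.csv(file.path(run_dir, "strata.csv"))

  group_rows <- list()
  if (nrow(hits) > 0) {
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      subjects <- strata_df$subject_id[strata_df$stratum == h$stratum]
      m19 <- mean19[mean19$phenotype == h$phenotype &
                      mean19$intensity == h$intensity &
                      mean19$subject_id %in% subjects, ]
      gs <- genotype_group_summary(
        stats::setNames(m19$mean_19h, m19$subject_id),
        dosages[intersect(subjects, rownames(dosages)), h$variant_id])
      gr <- gs$groups
      gr$variant_id <- h$variant_id
      gr$phenotype <- h$phenotype
      gr$intensity <- h$intensity
      gr$stratum <- h$stratum
      group_rows[[i]] <- gr
    }
  }
  group_table <- if (length(group_rows)) do.call(rbind, group_rows) else
    data.frame()

  fm_path <- file.path(run_dir, "final_models.json")
  model_table <- data.frame()
  if (file.exists(fm_path)) {
    fm <- jsonlite::read_json(fm_path)
    if (length(fm) > 0) {
      model_table <- do.call(rbind, lapply(names(fm), function(k) {
        f <- fm[[k]]
        est <- unlist(f$reml_beta)
        data.frame(model = k, variant_id = f$variant_id, coding = f$coding,
                   correlation = f$correlation,
                   equation = paste(sprintf("%+.4f*%s", est, names(est)),
                                    collapse = " "),
                   pve_covariates_only = f$pve_covariates_only,
                   partial_pve_snp = f$partial_pve_snp,
                   lrt_p_snp = f$lrt_p_snp)
      }))
    }
  }
  list(group_table = group_table, model_table = model_table)
}
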