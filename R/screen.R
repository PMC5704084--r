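#' Screen one variant against the hourly response
#'
#' Fits the stage-1 screening model for a single dosage vector: generalized
#' least squares with AR(1) within-subject correlation by ML, mean model
#' `1 + t + t^2 + t^3 + SNP + SNP*t + SNP*t^2 + SNP*t^3` with the variant
#' under additive (#MA) coding. The variant p-value is the joint test of all
#' SNP terms, by likelihood ratio against the time-only model (default) or
#' by Wald F on residual degrees of freedom. Subjects with missing dosage are
#' dropped (complete-case per variant). If the SNP-by-time columns make the
#' design singular (e.g. a lone carrier observed at too few hours), the model
#' falls back to the SNP main effect only and the record is flagged.
#'
#' @param dosage named numeric vector of minor-allele dosages, names =
#'   subject ids.
#' @param responses data frame with `subject_id`, `hour`, `response` for one
#'   phenotype, intensity and stratum.
#' @param test `"LRT"` or `"WaldF"`.
#' @param reduced_fit optional pre-computed time-only `gls_fit` on exactly
#'   the same rows (cache for screening many variants with identical
#'   complete-case sets); ignored for Wald tests.
#' @return list with `p_raw`, `fit`, `reduced`, `snp_df`, `snp_terms`,
#'   `fallback`, `n_subjects`; or `list(skipped = TRUE, reason = ...)` when
#'   the variant is monomorphic on the available subjects.
#' @export
screen_one <- function(dosage, responses, test = c("LRT", "WaldF"),
                       reduced_fit = NULL) {
  test <- match.arg(test)
  stopifnot(all(c("subject_id", "hour", "response") %in% names(responses)))
  dosage <- dosage[!is.na(dosage)]
  d <- responses[responses$subject_id %in% names(dosage), , drop = FALSE]
  if (nrow(d) == 0) return(list(skipped = TRUE, reason = "no overlapping subjects"))
  dos <- dosage[as.character(d$subject_id)]
  if (length(unique(dosage[unique(as.character(d$subject_id))])) < 2) {
    return(list(skipped = TRUE, reason = "monomorphic in stratum"))
  }
  d <- data.frame(subject_id = d$subject_id, hour = d$hour,
                  response = d$response,
                  t1 = d$hour, t2 = d$hour^2, t3 = d$hour^3,
                  snp = as.numeric(dos))
  d$snp_t1 <- d$snp * d$t1
  d$snp_t2 <- d$snp * d$t2
  d$snp_t3 <- d$snp * d$t3

  full_formula <- response ~ t1 + t2 + t3 + snp + snp_t1 + snp_t2 + snp_t3
  snp_terms <- c("snp", "snp_t1", "snp_t2", "snp_t3")
  fallback <- FALSE
  fit <- tryCatch(
    fit_gls(full_formula, d, correlation = "AR1", method = "ML"),
    pehgene_rank_error = function(e) NULL)
  if (is.null(fit)) {
    fallback <- TRUE
    snp_terms <- "snp"
    fit <- fit_gls(response ~ t1 + t2 + t3 + snp, d,
                   correlation = "AR1", method = "ML")
  }

  if (test == "LRT") {
    if (is.null(reduced_fit) || reduced_fit$n_obs != fit$n_obs) {
      reduced_fit <- fit_gls(response ~ t1 + t2 + t3, d,
                             correlation = "AR1", method = "ML")
    }
    p_raw <- lrt(fit, reduced_fit)$p
  } else {
    reduced_fit <- NULL
    p_raw <- wald_p_residual_df(fit, snp_terms)$p
  }
  list(p_raw = p_raw, fit = fit, reduced = reduced_fit,
       snp_df = length(snp_terms), snp_terms = snp_terms,
       fallback = fallback,
       n_subjects = length(unique(d$subject_id)), skipped = FALSE)
}

#' Bonferroni adjustment over unique genotype profiles
#'
#' @param p_raw raw p-value(s).
#' @param m number of unique genotype profiles in the stratum (family size).
#' @export
adjust_bonferroni <- function(p_raw, m) {
  stopifnot(m >= 1)
  pmin(1, p_raw * m)
}

#' Benjamini-Yekutieli adjustment over unique genotype profiles
#'
#' Step-up FDR adjustment valid under arbitrary dependence:
#' \eqn{\tilde p_{(i)} = \min(1, \min_{j \ge i} p_{(j)} m c(m) / j)} with
#' \eqn{c(m) = \sum_{k=1}^m 1/k}. One p-value per profile group is expected,
#' so the vector length must equal `m`. Delegates to
#' `stats::p.adjust(method = "BY")`.
#'
#' @param p vector of raw p-values, one per profile group.
#' @param m family size; must equal `length(p)`.
#' @return adjusted p-values in input order.
#' @export
adjust_by <- function(p, m) {
  if (length(p) != m) {
    stop("expected one p-value per profile group: length(p) = ", length(p),
         " but m = ", m)
  }
  stats::p.adjust(p, method = "BY")
}

#' Select screening hits
#'
#' A record is a hit iff its Bonferroni-adjusted p-value is < `bonferroni`
#' or its BY-adjusted p-value is < `by` (strict inequalities).
#'
#' @param records screening records data frame with `p_bonferroni`, `p_by`.
#' @param bonferroni,by selection thresholds.
#' @export
select_hits <- function(records, bonferroni = 0.05, by = 0.25) {
  stopifnot(all(c("p_bonferroni", "p_by") %in% names(records)))
  records[records$p_bonferroni < bonferroni | records$p_by < by, , drop = FALSE]
}

#' Genotype-group summary of the 19-h-averaged response
#'
#' For each #MA group: subject count, mean and sample SD (n-1 denominator;
#' SD is `NA` for a single subject) of the subject-level BP response averaged
#' over 19 h. The extreme-group effect is the mean of the highest observed
#' #MA group minus the mean of the 0-MA group, in mmHg.
#'
#' @param mean_19h named numeric vector of 19-h-averaged responses, names =
#'   subject ids.
#' @param dosage named dosage vector over the same subjects.
#' @return list with `groups` (data frame: `dosage`, `n`, `mean`, `sd`) and
#'   `effect_extreme` (`NA` with a warning when there is no 0-MA group).
#' @export
genotype_group_summary <- function(mean_19h, dosage) {
  common <- intersect(names(mean_19h), names(dosage)[!is.na(dosage)])
  if (length(common) == 0) stop("no subjects with both response and dosage")
  x <- mean_19h[common]
  g <- dosage[common]
  groups <- do.call(rbind, lapply(sort(unique(g)), function(d) {
    v <- x[g == d]
    data.frame(dosage = d, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
  if (!0 %in% groups$dosage) {
    warning("no 0-MA group; extreme-group effect undefined")
    effect <- NA_real_
  } else {
    hi <- max(groups$dosage)
    effect <- groups$mean[groups$dosage == hi] - groups$mean[groups$dosage == 0]
  }
  list(groups = groups, effect_extreme = effect)
}

#' Screen all variants within ethnic strata
#'
#' Runs the stage-1 screen per stratum, phenotype and intensity: collapses
#' variants into unique genotype profiles, fits one screening model per
#' profile group, adjusts the group p-values by Bonferroni and BY over the
#' stratum's `m` profiles, and copies the group results to each member
#' variant.
#'
#' @param responses tidy response data frame from [compute_responses()]
#'   (`subject_id`, `intensity`, `phenotype`, `hour`, `response`).
#' @param mean_19h per-subject 19-h-averaged responses (same source).
#' @param dosages subjects x variants minor-allele dosage matrix.
#' @param strata named character vector, subject id to stratum label.
#' @param phenotypes,intensities which response series to screen.
#' @param test joint SNP test passed to [screen_one()].
#' @return data frame of screening records, one row per variant x stratum x
#'   phenotype x intensity, with columns `p_raw`, `p_bonferroni`, `p_by`,
#'   `m`, `snp_df`, `fallback`, `effect_extreme` and group counts; skipped
#'   (monomorphic) variants are omitted.
#' @export
screen_variants <- function(responses, mean_19h, dosages, strata,
                            phenotypes = c("SBP", "DBP"),
                            intensities = c("MODERATE", "VIGOROUS"),
                            test = c("LRT", "WaldF")) {
  test <- match.arg(test)
  out <- list()
  for (stratum in unique(strata)) {
    subjects <- names(strata)[strata == stratum]
    prof <- unique_profiles(dosages, subjects)
    if (prof$m == 0) next
    for (phen in phenotypes) {
      for (intensity in intensities) {
        rows <- responses[responses$phenotype == phen &
                            responses$intensity == intensity &
                            responses$subject_id %in% subjects, , drop = FALSE]
        if (nrow(rows) == 0) next
        m19 <- mean_19h[mean_19h$phenotype == phen &
                          mean_19h$intensity == intensity &
                          mean_19h$subject_id %in% subjects, , drop = FALSE]
        m19v <- stats::setNames(m19$mean_19h, m19$subject_id)

        reduced_cache <- list()
        group_res <- lapply(prof$groups, function(gr) {
          dos <- gr$dosages
          key <- paste(sort(names(dos)[!is.na(dos)]), collapse = ",")
          sc <- screen_one(dos, rows, test = test,
                           reduced_fit = reduced_cache[[key]])
          if (!isTRUE(sc$skipped) && !is.null(sc$reduced)) {
            reduced_cache[[key]] <<- sc$reduced
          }
          sc
        })
        keep <- !vapply(group_res, function(g) isTRUE(g$skipped), logical(1))
        if (!any(keep)) next
        p_group <- vapply(group_res[keep], `[[`, numeric(1), "p_raw")
        # family = all m profile groups of this stratum; groups unfittable on
        # this response subset still count toward m
        p_bonf <- adjust_bonferroni(p_group, prof$m)
        p_by_full <- rep(1, prof$m)
        p_by_full[which(keep)] <- p_group
        p_by <- adjust_by(p_by_full, prof$m)[which(keep)]

        kept_groups <- prof$groups[keep]
        kept_res <- group_res[keep]
        for (gi in seq_along(kept_groups)) {
          gr <- kept_groups[[gi]]
          gs <- genotype_group_summary(m19v, gr$dosages)
          for (vid in gr$member_variant_ids) {
            out[[length(out) + 1L]] <- data.frame(
              variant_id = vid, profile_key = gr$profile_key,
              stratum = stratum, phenotype = phen, intensity = intensity,
              n_subjects = kept_res[[gi]]$n_subjects,
              snp_df = kept_res[[gi]]$snp_df,
              fallback = kept_res[[gi]]$fallback,
              p_raw = p_group[gi], p_bonferroni = p_bonf[gi], p_by = p_by[gi],
              m = prof$m, effect_extreme = gs$effect_extreme,
              n_groups = nrow(gs$groups))
          }
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(variant_id = character(), profile_key = character(),
                      stratum = character(), phenotype = character(),
                      intensity = character(), n_subjects = integer(),
                      snp_df = integer(), fallback = logical(),
                      p_raw = numeric(), p_bonferroni = numeric(),
                      p_by = numeric(), m = integer(),
                      effect_extreme = numeric(), n_groups = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extreme-group effects from a genotype-group summary table
#'
#' Computes the extreme-group effect (mean response of the highest observed
#' #MA group minus the 0-MA group) for each variant and phenotype in a group
#' summary table, by expanding each group to its subject-level mean and
#' delegating to [genotype_group_summary()]. Useful for reference tables
#' that print only per-group n, mean and SD.
#'
#' @param tbl data frame with columns `variant`, `phenotype`, `dosage`, `n`,
#'   `mean` (one row per genotype group).
#' @return data frame with `variant`, `phenotype`, `effect_extreme`.
#' @export
effect_from_group_table <- function(tbl) {
  stopifnot(all(c("variant", "phenotype", "dosage", "n", "mean") %in% names(tbl)))
  combos <- unique(tbl[, c("variant", "phenotype")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- tbl[tbl$variant == combos$variant[i] &
                 tbl$phenotype == combos$phenotype[i], ]
    vals <- unlist(lapply(seq_len(nrow(sub)), function(j) rep(sub$mean[j], sub$n[j])))
    dos <- unlist(lapply(seq_len(nrow(sub)), function(j) rep(sub$dosage[j], sub$n[j])))
    ids <- paste0("s", seq_along(vals))
    gs <- genotype_group_summary(stats::setNames(vals, ids),
                                 stats::setNames(dos, ids))
    data.frame(variant = combos$variant[i], phenotype = combos$phenotype[i],
               effect_extreme = gs$effect_extreme)
  })
  do.call(rbind, out)
}
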