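#' Prepare covariates on the modelling scale
#'
#' Applies natural-log transforms to the skewed covariates and centers every
#' covariate at the sample mean of the supplied subjects (covariates are
#' centered in the final models; the polymorphism is not).
#'
#' @param covariates covariate data frame with `subject_id`.
#' @param candidates covariate column names to prepare.
#' @param log_covariates subset of `candidates` to log-transform (before
#'   centering).
#' @param center logical; subtract the sample mean.
#' @return list with `data` (subject_id plus transformed columns) and
#'   `centers` (named vector of subtracted means, on the transformed scale).
#' @export
prep_covariates <- function(covariates,
                            candidates = c("age", "gender", "bmi", "aasi",
                                           "orient_sbp", "tg", "endothelin",
                                           "insulin"),
                            log_covariates = c("aasi", "tg", "endothelin",
                                               "insulin"),
                            center = TRUE) {
  stopifnot("subject_id" %in% names(covariates))
  candidates <- intersect(candidates, names(covariates))
  out <- data.frame(subject_id = covariates$subject_id)
  centers <- stats::setNames(numeric(length(candidates)), candidates)
  for (cv in candidates) {
    x <- covariates[[cv]]
    if (cv %in% log_covariates) {
      if (any(x <= 0, na.rm = TRUE)) {
        stop("covariate ", cv, " has non-positive values; cannot log-transform")
      }
      x <- log(x)
    }
    ctr <- if (center) mean(x, na.rm = TRUE) else 0
    centers[cv] <- ctr
    out[[cv]] <- x - ctr
  }
  list(data = out, centers = centers)
}

#' Marginal covariate eligibility screen
#'
#' Each candidate covariate is tested alone (plus intercept) against the
#' hourly response under an AR(1) ML fit; covariates marginally associated
#' (Wald p < 0.05 on residual df) are eligible for the final models.
#'
#' @param responses stacked rows (`subject_id`, `hour`, `response`) for one
#'   phenotype, intensity and stratum.
#' @param covariates covariate data frame (raw scale) with `subject_id`.
#' @param candidates,log_covariates see [prep_covariates()].
#' @param alpha eligibility threshold.
#' @return data frame with `covariate`, `beta`, `p`, `eligible`; constant
#'   covariates are skipped with a warning.
#' @export
marginal_covariate_screen <- function(responses, covariates,
                                      candidates = c("age", "gender", "bmi",
                                                     "aasi", "orient_sbp",
                                                     "tg", "endothelin",
                                                     "insulin"),
                                      log_covariates = c("aasi", "tg",
                                                         "endothelin",
                                                         "insulin"),
                                      alpha = 0.05) {
  prep <- prep_covariates(covariates, candidates, log_covariates)
  rows <- merge(responses, prep$data, by = "subject_id")
  out <- list()
  for (cv in setdiff(names(prep$data), "subject_id")) {
    if (stats::var(prep$data[[cv]], na.rm = TRUE) == 0) {
      warning("covariate ", cv, " is constant; skipped")
      next
    }
    f <- stats::as.formula(paste("response ~", cv))
    fit <- fit_gls(f, rows, correlation = "AR1", method = "ML")
    w <- wald_p_residual_df(fit, cv)
    out[[cv]] <- data.frame(covariate = cv, beta = unname(fit$beta[cv]),
                            p = w$p, eligible = w$p < alpha)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  if (is.null(res)) res <- data.frame(covariate = character(), beta = numeric(),
                                      p = numeric(), eligible = logical())
  res
}

# assemble the modelling frame: responses + prepared covariates + snp codings
.model_frame <- function(responses, dosage, prep_data) {
  d <- responses[responses$subject_id %in% names(dosage)[!is.na(dosage)], ,
                 drop = FALSE]
  d <- merge(d, prep_data, by = "subject_id")
  d$t1 <- d$hour
  d$t2 <- d$hour^2
  d$t3 <- d$hour^3
  d$snp_add <- as.numeric(dosage[as.character(d$subject_id)])
  d$snp_dom <- dominant_recode(d$snp_add)
  d
}

.fit_terms <- function(terms, data, correlation = "AR1", method = "ML") {
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  fit_gls(stats::as.formula(paste("response ~", rhs)), data,
          correlation = correlation, method = method)
}

#' Build the final multivariable model for a screening hit
#'
#' Stage-2 model building: forward selection by ML AIC over the eligible
#' covariates and the order of the time polynomial (0..3, powers entered
#' sequentially); choice of additive vs dominant genetic coding and of
#' SNP-by-time interactions by ML AIC; choice of within-subject correlation
#' structure among independence, compound symmetry and AR(1) by ML AIC at
#' the selected mean model; REML refit for the reported estimates; and a
#' joint ML likelihood-ratio test of the polymorphism terms. Ties in AIC
#' (within 1e-6) prefer the smaller model, then earlier candidate order.
#'
#' @param responses stacked rows (`subject_id`, `hour`, `response`).
#' @param dosage named minor-allele dosage vector.
#' @param covariates covariate data frame (raw scale).
#' @param candidates,log_covariates candidate covariates; see
#'   [prep_covariates()].
#' @param variant_id label carried into the result.
#' @return object of class `"final_model"`: selected `terms`, `coding`,
#'   `correlation`, `reml_beta`, `pve_covariates_only`, `partial_pve_snp`,
#'   `lrt_p_snp`, `eligibility` table, `centers`, `log_covariates`,
#'   `n_subjects`.
#' @export
select_model <- function(responses, dosage, covariates,
                         candidates = c("age", "gender", "bmi", "aasi",
                                        "orient_sbp", "tg", "endothelin",
                                        "insulin"),
                         log_covariates = c("aasi", "tg", "endothelin",
                                            "insulin"),
                         variant_id = NA_character_) {
  eligibility <- marginal_covariate_screen(responses, covariates, candidates,
                                           log_covariates)
  eligible <- eligibility$covariate[eligibility$eligible]
  prep <- prep_covariates(covariates, candidates, log_covariates)
  d <- .model_frame(responses, dosage, prep$data)
  if (length(unique(d$snp_add)) < 2) stop("variant monomorphic on modelled subjects")

  ## forward AIC selection of covariates and time polynomial order
  time_terms <- c("t1", "t2", "t3")
  current <- character(0)
  best <- .fit_terms(current, d)
  repeat {
    n_time <- sum(time_terms %in% current)
    cands <- c(if (n_time < 3) time_terms[n_time + 1],
               setdiff(sort(eligible), current))
    if (length(cands) == 0) break
    fits <- lapply(cands, function(tm) .fit_terms(c(current, tm), d))
    aics <- vapply(fits, `[[`, numeric(1), "aic")
    j <- which(aics <= min(aics) + 1e-6)[1]
    if (aics[j] < best$aic - 1e-6) {
      current <- c(current, cands[j])
      best <- fits[[j]]
    } else break
  }
  mean_terms <- current

  ## genetic coding and SNP-by-time interactions, by AIC
  sel_time <- intersect(time_terms, mean_terms)
  snp_opts <- list(
    list(coding = "additive", terms = "snp_add"),
    list(coding = "dominant", terms = "snp_dom"))
  if (length(sel_time) > 0) {
    for (coding in c("additive", "dominant")) {
      base <- if (coding == "additive") "snp_add" else "snp_dom"
      inter <- paste0(base, "_x_", sel_time)
      for (k in seq_along(inter)) d[[inter[k]]] <- d[[base]] * d[[sel_time[k]]]
      snp_opts[[length(snp_opts) + 1L]] <- list(coding = coding,
                                                terms = c(base, inter))
    }
  }
  snp_fits <- lapply(snp_opts, function(o) {
    tryCatch(.fit_terms(c(mean_terms, o$terms), d),
             pehgene_rank_error = function(e) NULL)
  })
  ok <- !vapply(snp_fits, is.null, logical(1))
  if (!any(ok)) stop("no admissible polymorphism model (singular designs)")
  snp_opts <- snp_opts[ok]
  snp_fits <- snp_fits[ok]
  aics <- vapply(snp_fits, `[[`, numeric(1), "aic")
  sizes <- lengths(lapply(snp_opts, `[[`, "terms"))
  near <- which(aics <= min(aics) + 1e-6)
  j <- near[order(sizes[near], near)][1]
  snp_terms <- snp_opts[[j]]$terms
  coding <- snp_opts[[j]]$coding
  full_terms <- c(mean_terms, snp_terms)

  ## correlation structure by AIC at the selected mean model
  struct_cands <- c("IND", "CS", "AR1")
  struct_fits <- lapply(struct_cands, function(s) .fit_terms(full_terms, d, correlation = s))
  s_aic <- vapply(struct_fits, `[[`, numeric(1), "aic")
  si <- which(s_aic <= min(s_aic) + 1e-6)[1]
  structure_sel <- struct_cands[si]

  full_ml <- .fit_terms(full_terms, d, correlation = structure_sel, method = "ML")
  cov_ml <- .fit_terms(mean_terms, d, correlation = structure_sel, method = "ML")
  int_ml <- .fit_terms(character(0), d, correlation = structure_sel, method = "ML")
  reml <- .fit_terms(full_terms, d, correlation = structure_sel, method = "REML")

  n_subj <- full_ml$n_subjects
  pve <- report_pve(full_ml, cov_ml, int_ml)

  structure(list(
    variant_id = variant_id,
    terms = full_terms, snp_terms = snp_terms, coding = coding,
    correlation = structure_sel,
    reml_beta = reml$beta, rho = reml$rho, sigma2 = reml$sigma2,
    pve_covariates_only = pve$pve_covariates_only,
    partial_pve_snp = pve$partial_pve_snp,
    lrt_p_snp = lrt(full_ml, cov_ml)$p,
    loglik = c(full = full_ml$loglik, covariates = cov_ml$loglik,
               intercept = int_ml$loglik),
    eligibility = eligibility,
    centers = prep$centers, log_covariates = log_covariates,
    n_subjects = n_subj, n_obs = full_ml$n_obs
  ), class = "final_model")
}

#' @export
print.final_model <- function(x, ...) {
  cat("Final model", if (!is.na(x$variant_id)) paste0("(", x$variant_id, ")"),
      "-", x$coding, "coding,", x$correlation, "correlation\n")
  cat("  terms:", paste(x$terms, collapse = " + "), "\n")
  cat("  partial PVE (variant):", format(x$partial_pve_snp, digits = 4),
      "  LRT p:", format(x$lrt_p_snp, digits = 4), "\n")
  invisible(x)
}

#' Proportion of variance explained, with and without the variant
#'
#' @param full_fit,covariates_only_fit,intercept_only_fit ML `gls_fit`s on
#'   identical rows.
#' @return list with `pve_covariates_only` (pseudo-R2 of the no-variant
#'   model) and `partial_pve_snp` (increment from the variant terms).
#' @export
report_pve <- function(full_fit, covariates_only_fit, intercept_only_fit) {
  n_obs <- c(full_fit$n_obs, covariates_only_fit$n_obs, intercept_only_fit$n_obs)
  if (length(unique(n_obs)) != 1) stop("fits use different rows")
  n <- full_fit$n_subjects
  list(
    pve_covariates_only = pseudo_r2(intercept_only_fit$loglik,
                                    covariates_only_fit$loglik, n),
    partial_pve_snp = partial_pve(full_fit, covariates_only_fit,
                                  intercept_only_fit))
}

#' Predict the hourly response from a final model
#'
#' Evaluates the linear predictor of a fitted final model. Covariate values
#' must be supplied on the model's scale (logged where the model logs them,
#' centered: a value of 0 means "at the sample mean").
#'
#' @param result a [select_model()] result (or any list with `reml_beta`,
#'   `snp_terms`, `coding`).
#' @param covariate_values named list/vector of centered covariate values.
#' @param dosage minor-allele dosage (0, 1, 2); recoded internally if the
#'   model uses dominant coding.
#' @param hour hour index 1..19.
#' @return predicted response, mmHg.
#' @export
predict_response <- function(result, covariate_values = list(), dosage = 0,
                             hour = 1) {
  beta <- result$reml_beta
  snp_val <- if (identical(result$coding, "dominant")) {
    dominant_recode(dosage)
  } else dosage
  vals <- numeric(length(beta))
  names(vals) <- names(beta)
  for (nm in names(beta)) {
    vals[nm] <- if (nm == "(Intercept)") 1
    else if (nm == "t1") hour
    else if (nm == "t2") hour^2
    else if (nm == "t3") hour^3
    else if (nm %in% c("snp_add", "snp_dom")) snp_val
    else if (grepl("^snp_(add|dom)_x_t[123]$", nm)) {
      k <- as.integer(sub(".*t", "", nm))
      snp_val * hour^k
    } else {
      if (!nm %in% names(covariate_values)) {
        stop("missing covariate value: ", nm)
      }
      covariate_values[[nm]]
    }
  }
  sum(beta * vals)
}
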