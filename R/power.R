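#' Specification for simulation-based power estimation
#'
#' @param n_subjects subjects per simulated dataset.
#' @param geno_probs probabilities of 0, 1 and 2 minor alleles (observed
#'   genotype-class proportions, or Hardy-Weinberg from a MAF via
#'   `hwe_probs()`).
#' @param beta named coefficient vector of the screening-model mean
#'   structure; recognised names are `intercept`, `t1`, `t2`, `t3`, `snp`,
#'   `snp_t1`, `snp_t2`, `snp_t3` (absent terms are zero).
#' @param rho,sigma2 AR(1) correlation and residual variance of the hourly
#'   errors.
#' @param n_sims number of simulated datasets.
#' @param alpha significance level; the screening default is the Bonferroni
#'   level 0.05 / m over the stratum's unique genotype profiles.
#' @param hours hour indices (19 hourly values).
#' @export
power_spec <- function(n_subjects, geno_probs, beta, rho, sigma2,
                       n_sims = 1000, alpha = 0.05 / 300, hours = 1:19) {
  stopifnot(n_subjects >= 2, length(geno_probs) == 3, all(geno_probs >= 0),
            abs(sum(geno_probs) - 1) < 1e-8, abs(rho) < 1, sigma2 > 0,
            n_sims >= 1, alpha > 0, alpha <= 1)
  structure(list(n_subjects = n_subjects, geno_probs = geno_probs,
                 beta = beta, rho = rho, sigma2 = sigma2, n_sims = n_sims,
                 alpha = alpha, hours = hours), class = "power_spec")
}

#' Hardy-Weinberg genotype-class probabilities from a MAF
#' @param maf minor-allele frequency.
#' @export
hwe_probs <- function(maf) {
  stopifnot(maf >= 0, maf <= 0.5)
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

#' Simulation-based power of the variant screen
#'
#' For each simulated dataset: genotypes are drawn from the genotype-class
#' distribution (monomorphic draws are redrawn up to 100 times, then counted
#' as non-converged), 19 hourly responses per subject are simulated from the
#' screening-model mean structure with AR(1) errors, the screening model is
#' refitted, and the joint SNP terms are tested by Wald F on residual
#' degrees of freedom. Power is the fraction of converged simulations with
#' p < alpha.
#'
#' @param spec a [power_spec()].
#' @param seed integer seed; results are deterministic given `seed`.
#' @return list of class `"power_result"`: `power`, `mc_se`
#'   (`sqrt(power (1 - power) / n_converged)`), `n_converged`, `n_sims`,
#'   `alpha`, `seed`.
#' @export
estimate_power <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "power_spec"))
  set.seed(seed)
  hours <- spec$hours
  nh <- length(hours)
  b <- function(nm) if (nm %in% names(spec$beta)) spec$beta[[nm]] else 0
  time_mean <- b("intercept") + b("t1") * hours + b("t2") * hours^2 +
    b("t3") * hours^3
  snp_prof <- b("snp") + b("snp_t1") * hours + b("snp_t2") * hours^2 +
    b("snp_t3") * hours^3
  sd_h <- sqrt(spec$sigma2)

  n_sig <- 0L
  n_conv <- 0L
  for (s in seq_len(spec$n_sims)) {
    dos <- NULL
    for (try in seq_len(100)) {
      cand <- sample(0:2, spec$n_subjects, replace = TRUE, prob = spec$geno_probs)
      if (length(unique(cand)) >= 2) { dos <- cand; break }
    }
    if (is.null(dos)) next

    y <- unlist(lapply(seq_len(spec$n_subjects), function(i) {
      time_mean + dos[i] * snp_prof + ar1_series(nh, spec$rho, sd_h)
    }))
    d <- data.frame(subject_id = rep(seq_len(spec$n_subjects), each = nh),
                    hour = rep(hours, spec$n_subjects), response = y)
    sc <- tryCatch(
      screen_one(stats::setNames(dos, seq_len(spec$n_subjects)), d,
                 test = "WaldF"),
      error = function(e) NULL)
    if (is.null(sc) || isTRUE(sc$skipped)) next
    n_conv <- n_conv + 1L
    if (sc$p_raw < spec$alpha) n_sig <- n_sig + 1L
  }
  if (n_conv == 0) stop("no simulation converged")
  power <- n_sig / n_conv
  structure(list(power = power,
                 mc_se = sqrt(power * (1 - power) / n_conv),
                 n_converged = n_conv, n_sims = spec$n_sims,
                 alpha = spec$alpha, seed = seed), class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Power %.3f (MC SE %.3f) from %d/%d converged simulations at alpha %.2e\n",
              x$power, x$mc_se, x$n_converged, x$n_sims, x$alpha))
  invisible(x)
}

#' Power across a grid of SNP effect sizes
#'
#' Runs [estimate_power()] at each value of the SNP main effect, offsetting
#' the seed deterministically per grid point.
#'
#' @param spec a [power_spec()]; its `beta["snp"]` entry is replaced by each
#'   grid value.
#' @param effects numeric vector of SNP main effects (mmHg per minor allele).
#' @param seed base seed; grid point j uses `seed + j - 1`.
#' @return list of `power_result`s, named by effect.
#' @export
power_curve <- function(spec, effects, seed = 1) {
  stopifnot(length(effects) >= 1)
  out <- lapply(seq_along(effects), function(j) {
    sj <- spec
    sj$beta[["snp"]] <- effects[j]
    estimate_power(sj, seed = seed + j - 1)
  })
  names(out) <- as.character(effects)
  out
}
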