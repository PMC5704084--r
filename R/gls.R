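#' Generalized least squares with subject-blocked correlation
#'
#' Fits a linear model to stacked longitudinal rows (one row per subject and
#' hour) assuming residuals are correlated within subject and independent
#' across subjects. The within-subject correlation matrix is AR(1)
#' (`rho^|t_s - t_t|` on the hour index, so missing hours contribute
#' `rho^gap`), compound symmetry (constant off-diagonal `rho`), or the
#' identity. The correlation parameter is estimated by maximising the profiled
#' ML or REML log-likelihood, with the coefficients and residual variance
#' concentrated out in closed form at each candidate `rho`.
#'
#' @param formula model formula, e.g. `response ~ hour + I(hour^2) + snp`.
#' @param data data frame of stacked rows. Rows with missing values in any
#'   model variable are dropped (complete-case).
#' @param subject,time names of the columns holding the subject identifier and
#'   the (numeric) time index.
#' @param correlation within-subject correlation family: `"AR1"`, `"CS"`
#'   (compound symmetry) or `"IND"` (independence, reduces to OLS).
#' @param method `"ML"` or `"REML"`. REML log-likelihoods include the
#'   \eqn{-\frac12 \log|X'R^{-1}X|} term; use ML fits for likelihood-ratio
#'   tests, AIC comparison across mean models, and pseudo-R-squared.
#' @param rho optional fixed correlation parameter; if supplied it is not
#'   estimated.
#' @param tol convergence tolerance for the one-dimensional profiled
#'   optimisation of `rho`.
#' @return an object of class `"gls_fit"`: a list with elements `beta`
#'   (named coefficient vector), `rho`, `sigma2`, `loglik`, `aic`, `n_obs`,
#'   `n_subjects`, `residual_df` (`n_obs` minus the number of mean
#'   parameters), `vcov`, `terms`, `correlation`, `method`.
#' @examples
#' d <- expand.grid(subject_id = 1:6, hour = 1:10)
#' set.seed(1)
#' d$y <- d$hour * 0.5 + rnorm(nrow(d))
#' fit_gls(y ~ hour, d, correlation = "IND")
#' @export
fit_gls <- function(formula, data, subject = "subject_id", time = "hour",
                    correlation = c("AR1", "CS", "IND"),
                    method = c("ML", "REML"),
                    rho = NULL, tol = 1e-9) {
  correlation <- match.arg(correlation)
  method <- match.arg(method)
  if (!is.data.frame(data)) stop("'data' must be a data frame")
  for (col in c(subject, time)) {
    if (!col %in% names(data)) stop("column '", col, "' not found in data")
  }

  vars <- all.vars(formula)
  absent <- setdiff(vars, names(data))
  if (length(absent) > 0) {
    stop("model variables absent from data: ", paste(absent, collapse = ", "))
  }
  keep <- stats::complete.cases(data[, unique(c(vars, subject, time)), drop = FALSE])
  d <- data[keep, , drop = FALSE]
  d <- d[order(d[[subject]], d[[time]]), , drop = FALSE]
  if (nrow(d) == 0) stop("no complete rows to fit")

  mf <- stats::model.frame(formula, d)
  X <- stats::model.matrix(formula, mf)
  y <- as.numeric(stats::model.response(mf))
  N <- length(y)
  p <- ncol(X)
  if (N <= p) stop("fewer observations (", N, ") than mean parameters (", p, ")")

  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    cond <- structure(
      class = c("pehgene_rank_error", "error", "condition"),
      list(message = paste0("design matrix is rank deficient; collinear terms: ",
                            paste(dropped, collapse = ", ")),
           call = sys.call(), dropped = dropped))
    stop(cond)
  }

  subj <- d[[subject]]
  tim <- as.numeric(d[[time]])
  idx <- split(seq_len(N), factor(subj, levels = unique(subj)))
  n_subjects <- length(idx)
  if (n_subjects < 2L) stop("need at least 2 subjects")
  if (correlation != "IND") {
    dup <- vapply(idx, function(ii) anyDuplicated(tim[ii]) > 0, logical(1))
    if (any(dup)) {
      stop("duplicated time points within subject(s) ",
           paste(names(idx)[dup], collapse = ", "),
           "; aggregate to one value per subject and time first")
    }
  }

  block_times <- lapply(idx, function(ii) tim[ii])
  kmax <- max(lengths(idx))
  gaps_integer <- all(vapply(block_times, function(t) {
    all(abs(diff(t) - round(diff(t))) < 1e-8)
  }, logical(1)))

  corr_mat <- function(t, r) {
    k <- length(t)
    switch(correlation,
           AR1 = r^abs(outer(t, t, "-")),
           CS = {
             M <- matrix(r, k, k)
             diag(M) <- 1
             M
           },
           IND = diag(k))
  }

  # Group subject blocks by time pattern: blocks sharing a pattern share the
  # correlation factorisation, so each pattern needs one triangular solve per
  # likelihood evaluation (columns of [X y] for all its subjects side by side).
  pat_key <- vapply(block_times, paste, character(1), collapse = ",")
  pat_groups <- split(seq_along(idx), pat_key)
  pat_data <- lapply(pat_groups, function(js) {
    k <- length(idx[[js[1]]])
    M <- matrix(0, k, (p + 1) * length(js))
    for (a in seq_along(js)) {
      ii <- idx[[js[a]]]
      M[, ((a - 1) * (p + 1) + 1):(a * (p + 1))] <-
        cbind(X[ii, , drop = FALSE], y[ii])
    }
    list(times = block_times[[js[1]]], M = M, n = length(js), k = k)
  })

  # Whitening transform: premultiply each block by L^-1 where R = L L'.
  whiten <- function(r) {
    logdet <- 0
    parts <- vector("list", length(pat_data))
    for (q in seq_along(pat_data)) {
      pd <- pat_data[[q]]
      if (pd$k == 1L || correlation == "IND") {
        Z <- pd$M
      } else {
        R <- corr_mat(pd$times, r)
        U <- tryCatch(chol(R), error = function(e) NULL)
        if (is.null(U)) return(NULL)
        Z <- forwardsolve(t(U), pd$M)
        logdet <- logdet + pd$n * 2 * sum(log(diag(U)))
      }
      dim(Z) <- c(pd$k, p + 1, pd$n)
      Z <- aperm(Z, c(1, 3, 2))
      dim(Z) <- c(pd$k * pd$n, p + 1)
      parts[[q]] <- Z
    }
    all_z <- do.call(rbind, parts)
    list(zX = all_z[, seq_len(p), drop = FALSE], zy = all_z[, p + 1],
         logdet = logdet)
  }

  profile_fit <- function(r) {
    w <- whiten(r)
    if (is.null(w)) return(NULL)
    qz <- qr(w$zX)
    beta <- qr.coef(qz, w$zy)
    res <- w$zy - drop(w$zX %*% beta)
    rss <- sum(res^2)
    if (method == "ML") {
      sigma2 <- rss / N
      ll <- -0.5 * (N * (log(2 * pi) + log(sigma2) + 1) + w$logdet)
    } else {
      sigma2 <- rss / (N - p)
      ldXX <- as.numeric(determinant(crossprod(w$zX), logarithm = TRUE)$modulus)
      ll <- -0.5 * ((N - p) * (log(2 * pi) + log(sigma2) + 1) + w$logdet + ldXX)
    }
    list(beta = beta, sigma2 = sigma2, loglik = ll, zX = w$zX)
  }

  negll <- function(r) {
    pf <- profile_fit(r)
    if (is.null(pf)) return(1e12)
    -pf$loglik
  }

  if (correlation == "IND") {
    rho_hat <- 0
  } else if (!is.null(rho)) {
    if (abs(rho) >= 1) stop("|rho| must be < 1")
    rho_hat <- rho
  } else {
    lo <- if (correlation == "CS") -1 / (kmax - 1) + 1e-6 else -0.999
    if (correlation == "AR1" && !gaps_integer) lo <- 1e-6
    hi <- 0.999
    grid <- seq(lo, hi, length.out = 21)
    vals <- vapply(grid, negll, numeric(1))
    i <- which.min(vals)
    bracket <- c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)])
    opt <- stats::optimize(negll, interval = bracket, tol = tol)
    rho_hat <- opt$minimum
    # optimize() can return an interior point marginally worse than a grid
    # endpoint; keep the better of the two
    if (negll(rho_hat) > vals[i]) rho_hat <- grid[i]
    # Brent is limited to ~sqrt(eps) in rho; a few Newton steps on the
    # central-difference score pin interior optima much tighter
    h <- 1e-4
    if (rho_hat - 2 * h > lo && rho_hat + 2 * h < hi) {
      for (it in 1:4) {
        f0 <- negll(rho_hat)
        fp <- negll(rho_hat + h)
        fm <- negll(rho_hat - h)
        g <- (fp - fm) / (2 * h)
        H <- (fp - 2 * f0 + fm) / h^2
        if (!is.finite(g) || !is.finite(H) || H <= 0) break
        step <- max(min(g / H, 0.05), -0.05)
        cand <- rho_hat - step
        if (cand <= lo + h || cand >= hi - h) break
        rho_hat <- cand
        if (abs(step) < 1e-10) break
      }
    }
  }

  pf <- profile_fit(rho_hat)
  if (is.null(pf)) stop("correlation matrix not positive definite at rho = ", rho_hat)
  xtx_inv <- chol2inv(chol(crossprod(pf$zX)))
  vcov <- pf$sigma2 * xtx_inv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  n_cov_par <- 1L + as.integer(correlation != "IND" && is.null(rho))

  structure(list(
    beta = stats::setNames(as.numeric(pf$beta), colnames(X)),
    terms = colnames(X),
    rho = if (correlation == "IND") NA_real_ else rho_hat,
    sigma2 = pf$sigma2,
    loglik = pf$loglik,
    aic = -2 * pf$loglik + 2 * (p + n_cov_par),
    n_obs = N,
    n_subjects = n_subjects,
    residual_df = N - p,
    vcov = vcov,
    correlation = correlation,
    method = method,
    formula = formula,
    fixed_rho = !is.null(rho),
    converged = TRUE
  ), class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat("Generalized least squares fit (", x$correlation, ", ", x$method, ")\n", sep = "")
  cat("  ", x$n_obs, " observations on ", x$n_subjects, " subjects\n", sep = "")
  if (!is.na(x$rho)) cat("  rho = ", format(x$rho, digits = 4), sep = "")
  cat("  sigma2 = ", format(x$sigma2, digits = 4),
      "  logLik = ", format(x$loglik, digits = 6),
      "  AIC = ", format(x$aic, digits = 6), "\n", sep = "")
  print(x$beta)
  invisible(x)
}

#' @export
logLik.gls_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) + 2, class = "logLik")
}

#' Likelihood ratio test between nested ML fits
#'
#' @param full,reduced `gls_fit` objects fitted by maximum likelihood on the
#'   same rows with the same correlation family; the reduced mean model must
#'   be nested in the full one.
#' @return list with `stat` (twice the log-likelihood difference, clipped at
#'   zero), `df` (difference in mean-parameter count) and `p` (chi-square
#'   upper tail).
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "gls_fit"), inherits(reduced, "gls_fit"))
  if (full$method != "ML" || reduced$method != "ML") {
    stop("likelihood ratio tests require ML fits (REML likelihoods are not comparable across mean models)")
  }
  if (full$n_obs != reduced$n_obs) {
    stop("fits use different rows (", full$n_obs, " vs ", reduced$n_obs, ")")
  }
  if (full$correlation != reduced$correlation) {
    stop("fits use different correlation families")
  }
  df <- length(full$beta) - length(reduced$beta)
  if (df < 0) stop("'full' has fewer mean parameters than 'reduced'")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(stat = stat, df = df, p = p)
}

#' Wald test on residual degrees of freedom
#'
#' Tests that a set of coefficients is jointly zero, referring the statistic
#' to an F distribution with denominator degrees of freedom equal to the
#' number of observations minus the number of mean parameters (for a single
#' coefficient this is the square of the usual t test).
#'
#' @param fit a `gls_fit`.
#' @param terms character vector of coefficient names to test jointly.
#' @return list with `stat` (F statistic), `df1`, `df2` (residual df) and `p`.
#' @details For ML fits the coefficient covariance is rescaled to the
#'   unbiased residual variance (`rss / (N - p)`), matching the classical
#'   t/F reference on `N - p` degrees of freedom; REML fits already use it.
#' @export
wald_p_residual_df <- function(fit, terms) {
  stopifnot(inherits(fit, "gls_fit"))
  missing_terms <- setdiff(terms, fit$terms)
  if (length(missing_terms) > 0) {
    stop("terms not in fit: ", paste(missing_terms, collapse = ", "))
  }
  b <- fit$beta[terms]
  V <- fit$vcov[terms, terms, drop = FALSE]
  if (fit$method == "ML") {
    V <- V * fit$n_obs / fit$residual_df
  }
  k <- length(terms)
  stat <- drop(crossprod(b, solve(V, b))) / k
  p <- stats::pf(stat, k, fit$residual_df, lower.tail = FALSE)
  list(stat = stat, df1 = k, df2 = fit$residual_df, p = p)
}

#' Likelihood-based proportion of variance explained
#'
#' Computes the pseudo-R-squared \eqn{R^2_m = 1 - (L_R / L_U)^{2/n}} where
#' `L_R` is the maximised likelihood of a restricted model (conventionally
#' intercept-only), `L_U` the maximised likelihood of the model of interest,
#' and `n` the number of subjects. Arguments are log-likelihoods.
#'
#' @param loglik_restricted,loglik_unrestricted maximised ML log-likelihoods.
#' @param n_subjects number of subjects.
#' @export
pseudo_r2 <- function(loglik_restricted, loglik_unrestricted, n_subjects) {
  stopifnot(n_subjects >= 1)
  if (loglik_unrestricted < loglik_restricted - 1e-8) {
    warning("unrestricted log-likelihood below restricted; R2m will be negative")
  }
  1 - exp((2 / n_subjects) * (loglik_restricted - loglik_unrestricted))
}

#' Partial proportion of variance explained by the variant terms
#'
#' The increment in pseudo-R-squared attributable to the polymorphism:
#' `pseudo_r2(full) - pseudo_r2(model without the variant terms)`, both
#' against the same intercept-only restricted fit.
#'
#' @param final_fit,fit_without_snp,intercept_only_fit ML `gls_fit`s on
#'   identical rows.
#' @param n_subjects number of subjects (defaults to the value in `final_fit`).
#' @export
partial_pve <- function(final_fit, fit_without_snp, intercept_only_fit,
                        n_subjects = final_fit$n_subjects) {
  fits <- list(final_fit, fit_without_snp, intercept_only_fit)
  stopifnot(all(vapply(fits, inherits, logical(1), "gls_fit")))
  n_obs <- vapply(fits, `[[`, numeric(1), "n_obs")
  if (length(unique(n_obs)) != 1) {
    stop("fits use different rows; refit on a common complete-case set")
  }
  pseudo_r2(intercept_only_fit$loglik, final_fit$loglik, n_subjects) -
    pseudo_r2(intercept_only_fit$loglik, fit_without_snp$loglik, n_subjects)
}
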