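# Independent brute-force oracles used across tests.

# Dense-covariance GLS: builds the full N x N correlation matrix explicitly,
# maximises the (ML or REML) log-likelihood over rho by one-dimensional
# search on dense-matrix formulas, and solves the closed-form GLS equations.
# Deliberately naive; shares no code with fit_gls().
oracle_gls <- function(X, y, subject, time, correlation = "AR1",
                       method = "ML", rho = NULL) {
  N <- length(y)
  p <- ncol(X)
  build_R <- function(r) {
    R <- matrix(0, N, N)
    for (s in unique(subject)) {
      ii <- which(subject == s)
      R[ii, ii] <- if (correlation == "AR1") {
        r^abs(outer(time[ii], time[ii], "-"))
      } else if (correlation == "CS") {
        M <- matrix(r, length(ii), length(ii)); diag(M) <- 1; M
      } else diag(length(ii))
    }
    R
  }
  eval_at <- function(r) {
    R <- build_R(r)
    Ri <- solve(R)
    XtRiX <- t(X) %*% Ri %*% X
    beta <- solve(XtRiX, t(X) %*% Ri %*% y)
    res <- y - X %*% beta
    rss <- drop(t(res) %*% Ri %*% res)
    ldR <- as.numeric(determinant(R, logarithm = TRUE)$modulus)
    if (method == "ML") {
      s2 <- rss / N
      ll <- -0.5 * (N * (log(2 * pi) + log(s2) + 1) + ldR)
    } else {
      s2 <- rss / (N - p)
      ldX <- as.numeric(determinant(XtRiX, logarithm = TRUE)$modulus)
      ll <- -0.5 * ((N - p) * (log(2 * pi) + log(s2) + 1) + ldR + ldX)
    }
    list(beta = drop(beta), sigma2 = s2, loglik = ll)
  }
  if (correlation == "IND") {
    out <- eval_at(0)
    out$rho <- NA_real_
    return(out)
  }
  if (!is.null(rho)) {
    out <- eval_at(rho)
    out$rho <- rho
    return(out)
  }
  kmax <- max(table(subject))
  lo <- if (correlation == "CS") -1 / (kmax - 1) + 1e-6 else -0.999
  nll <- function(r) -eval_at(r)$loglik
  opt <- stats::optimize(nll, interval = c(lo, 0.999), tol = 1e-10)
  r_hat <- opt$minimum
  # polish the interior optimum via the central-difference score
  h <- 1e-4
  if (r_hat - 2 * h > lo && r_hat + 2 * h < 0.999) {
    score <- function(r) (nll(r + h) - nll(r - h)) / (2 * h)
    s_lo <- score(r_hat - 10 * h)
    s_hi <- score(r_hat + 10 * h)
    if (is.finite(s_lo) && is.finite(s_hi) && sign(s_lo) != sign(s_hi)) {
      r_hat <- stats::uniroot(score, c(r_hat - 10 * h, r_hat + 10 * h),
                              tol = 1e-12)$root
    }
  }
  out <- eval_at(r_hat)
  out$rho <- r_hat
  out
}

# Hand step-up Benjamini-Yekutieli adjustment, written from the definition.
oracle_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  padj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    candidates <- vapply(i:m, function(j) p[o][j] * m * cm / j, numeric(1))
    padj_sorted[i] <- min(1, min(candidates))
  }
  out <- numeric(m)
  out[o] <- padj_sorted
  out
}

# Stacked-rows AR(1) test data with known parameters, at the GLS level.
make_ar1_data <- function(n_subjects, hours = 1:19, beta_time = c(0, 0, 0, 0),
                          rho = 0.6, sigma = 5, snp = NULL, snp_beta = 0) {
  nh <- length(hours)
  mean_t <- beta_time[1] + beta_time[2] * hours + beta_time[3] * hours^2 +
    beta_time[4] * hours^3
  rows <- lapply(seq_len(n_subjects), function(i) {
    e <- numeric(nh)
    e[1] <- rnorm(1, 0, sigma)
    if (nh > 1) for (t in 2:nh) {
      e[t] <- rho * e[t - 1] + rnorm(1, 0, sigma * sqrt(1 - rho^2))
    }
    s <- if (is.null(snp)) 0 else snp[i]
    data.frame(subject_id = i, hour = hours,
               response = mean_t + snp_beta * s + e)
  })
  do.call(rbind, rows)
}
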