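test_that("independence structure reproduces ordinary least squares", {
  set.seed(11)
  d <- make_ar1_data(6, hours = 1:10, rho = 0, sigma = 3,
                     beta_time = c(1, 0.5, 0, 0))
  fit <- fit_gls(response ~ hour, d, correlation = "IND")
  ols <- lm(response ~ hour, d)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-10)
  # ML residual variance: rss / N
  expect_equal(fit$sigma2, sum(resid(ols)^2) / nrow(d), tolerance = 1e-10)
  expect_equal(fit$residual_df, nrow(d) - 2)
})

test_that("AR1 fit with fixed rho equals the closed-form dense GLS solution", {
  set.seed(21)
  d <- make_ar1_data(2, hours = 1:3, rho = 0.5, sigma = 2)
  X <- cbind(1, d$hour)
  orc <- oracle_gls(X, d$response, d$subject_id, d$hour, rho = 0.5)
  fit <- fit_gls(response ~ hour, d, correlation = "AR1", rho = 0.5)
  expect_equal(unname(fit$beta), unname(orc$beta), tolerance = 1e-10)
  expect_equal(fit$sigma2, orc$sigma2, tolerance = 1e-10)
  expect_equal(fit$loglik, orc$loglik, tolerance = 1e-10)
})

test_that("estimated AR1/CS fits match the dense brute-force oracle", {
  set.seed(31)
  for (correlation in c("AR1", "CS")) {
    for (method in c("ML", "REML")) {
      d <- make_ar1_data(5, hours = 1:8, rho = 0.5, sigma = 4,
                         beta_time = c(2, -0.3, 0, 0))
      fit <- fit_gls(response ~ hour, d, correlation = correlation,
                     method = method)
      X <- cbind(1, d$hour)
      orc <- oracle_gls(X, d$response, d$subject_id, d$hour,
                        correlation = correlation, method = method)
      expect_equal(unname(fit$beta), unname(orc$beta), tolerance = 1e-8)
      expect_equal(fit$sigma2, orc$sigma2, tolerance = 1e-8)
      expect_equal(fit$rho, orc$rho, tolerance = 1e-6)
      expect_equal(fit$loglik, orc$loglik, tolerance = 1e-8)
    }
  }
})

test_that("unbalanced blocks (missing hours) use rho^gap, matching the dense oracle", {
  set.seed(41)
  d <- make_ar1_data(5, hours = 1:10, rho = 0.7, sigma = 3)
  d <- d[-c(3, 14, 27, 41), ]  # knock out scattered hours
  fit <- fit_gls(response ~ hour, d, correlation = "AR1", method = "ML")
  X <- cbind(1, d$hour)
  orc <- oracle_gls(X, d$response, d$subject_id, d$hour)
  expect_equal(unname(fit$beta), unname(orc$beta), tolerance = 1e-8)
  expect_equal(fit$rho, orc$rho, tolerance = 1e-6)
})

test_that("ML estimates agree with nlme::gls on a common dataset", {
  skip_if_not_installed("nlme")
  set.seed(51)
  d <- make_ar1_data(8, hours = 1:12, rho = 0.5, sigma = 3,
                     beta_time = c(1, 0.2, 0, 0))
  fit <- fit_gls(response ~ hour, d, correlation = "AR1", method = "ML")
  nl <- nlme::gls(response ~ hour, data = d,
                  correlation = nlme::corAR1(form = ~ hour | subject_id),
                  method = "ML")
  expect_equal(unname(fit$beta), unname(coef(nl)), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(nl)), tolerance = 1e-6)
  expect_equal(fit$aic, AIC(nl), tolerance = 1e-4)
  expect_equal(fit$rho, coef(nl$modelStruct$corStruct, unconstrained = FALSE)[[1]],
               tolerance = 1e-3)
})

test_that("profiled likelihood at the optimum dominates a rho grid", {
  set.seed(61)
  d <- make_ar1_data(6, hours = 1:10, rho = 0.4, sigma = 2)
  fit <- fit_gls(response ~ hour, d, correlation = "AR1", method = "ML")
  for (r in seq(-0.9, 0.9, by = 0.1)) {
    alt <- fit_gls(response ~ hour, d, correlation = "AR1", method = "ML",
                   rho = r)
    expect_gte(fit$loglik + 1e-8, alt$loglik)
  }
})

test_that("rank-deficient designs raise a typed error naming collinear terms", {
  d <- make_ar1_data(4, hours = 1:6, rho = 0, sigma = 1)
  d$x1 <- d$hour
  d$x2 <- 2 * d$hour
  err <- tryCatch(fit_gls(response ~ x1 + x2, d, correlation = "IND"),
                  pehgene_rank_error = function(e) e)
  expect_s3_class(err, "pehgene_rank_error")
  expect_match(conditionMessage(err), "x2")
})

test_that("likelihood ratio test matches the chi-square oracle and handles edge cases", {
  set.seed(71)
  d <- make_ar1_data(6, hours = 1:10, rho = 0.5, sigma = 3,
                     beta_time = c(1, 0.4, 0, 0))
  full <- fit_gls(response ~ hour + I(hour^2), d, correlation = "AR1")
  red <- fit_gls(response ~ hour, d, correlation = "AR1")
  out <- lrt(full, red)
  expect_equal(out$df, 1)
  expect_equal(out$stat, max(0, 2 * (full$loglik - red$loglik)))
  expect_equal(out$p, pchisq(out$stat, 1, lower.tail = FALSE))
  # identical models: stat 0, p 1
  same <- lrt(full, full)
  expect_equal(same$stat, 0)
  expect_equal(same$p, 1)
  # REML fits with different mean models are rejected
  full_reml <- fit_gls(response ~ hour + I(hour^2), d, correlation = "AR1",
                       method = "REML")
  red_reml <- fit_gls(response ~ hour, d, correlation = "AR1", method = "REML")
  expect_error(lrt(full_reml, red_reml), "ML")
})

test_that("Wald test on residual df matches the t-distribution oracle", {
  set.seed(81)
  d <- make_ar1_data(6, hours = 1:10, rho = 0, sigma = 2,
                     beta_time = c(0, 0.8, 0, 0))
  fit <- fit_gls(response ~ hour, d, correlation = "IND")
  w <- wald_p_residual_df(fit, "hour")
  # classical t: unbiased residual variance on N - p df (ML vcov rescaled)
  se <- sqrt(fit$vcov["hour", "hour"] * fit$n_obs / fit$residual_df)
  tstat <- fit$beta[["hour"]] / se
  expect_equal(w$p, 2 * pt(abs(tstat), fit$residual_df, lower.tail = FALSE),
               tolerance = 1e-12)
  # F(1, nu) is exactly t(nu)^2
  expect_equal(w$stat, tstat^2, tolerance = 1e-12)
  expect_error(wald_p_residual_df(fit, "nonexistent"), "not in fit")
})

test_that("pseudo-R2 evaluates the likelihood-ratio formula", {
  # L_R / L_U = 0.5 with n = 14: 1 - 0.5^(1/7)
  ll_u <- -100
  ll_r <- ll_u + log(0.5)
  expect_equal(pseudo_r2(ll_r, ll_u, 14), 1 - 0.5^(2 / 14), tolerance = 1e-12)
  expect_equal(pseudo_r2(ll_u, ll_u, 14), 0)
  # strictly increasing in the unrestricted log-likelihood
  r2 <- vapply(c(-99, -98, -97), function(l) pseudo_r2(ll_r, l, 14), numeric(1))
  expect_true(all(diff(r2) > 0))
  expect_warning(pseudo_r2(ll_u, ll_u - 1, 14), "negative")
})

test_that("partial PVE composes two pseudo-R2 calls", {
  set.seed(91)
  snp <- rep(c(0, 1, 2), length.out = 8)
  d <- make_ar1_data(8, hours = 1:10, rho = 0.4, sigma = 3,
                     snp = snp, snp_beta = -6)
  d$snp <- snp[d$subject_id]
  full <- fit_gls(response ~ hour + snp, d, correlation = "AR1")
  nosnp <- fit_gls(response ~ hour, d, correlation = "AR1")
  int <- fit_gls(response ~ 1, d, correlation = "AR1")
  pp <- partial_pve(full, nosnp, int)
  expect_equal(pp,
               pseudo_r2(int$loglik, full$loglik, 8) -
                 pseudo_r2(int$loglik, nosnp$loglik, 8), tolerance = 1e-12)
  expect_gte(pp, 0)
  expect_equal(partial_pve(full, full, int), 0)
})
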