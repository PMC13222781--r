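test_that("the model specification has the documented moment and parameter counts", {
  s3 <- build_mosla_spec(3)
  expect_identical(s3$df, 15L)
  expect_identical(s3$n_moments, 21L)
  expect_length(s3$observed, 6L)
  expect_length(s3$latent, 5L)
  expect_length(s3$free, 6L)

  s2 <- build_mosla_spec(2)
  expect_identical(s2$n_moments, 10L)
  expect_identical(s2$df, 4L)

  expect_error(build_mosla_spec(1), "waves")
})

test_that("the RAM implied covariance equals the closed form on random draws", {
  set.seed(7)
  for (i in 1:100) {
    p <- rand_mosla_params()
    w <- sample(2:4, 1)
    spec <- build_mosla_spec(w)
    ram <- mosla_implied_cov(spec, p)
    cf <- implied_cov_mosla(p, w)
    expect_lt(max(abs(ram - cf)), 1e-12)
  }
})

test_that("implied covariance degenerates as the model says at the edges", {
  # rho = 0, psi = 0: compound symmetry within construct
  p <- mosla_params(0.5, 0.3, 0.1, psi = 0, rho = 0, theta = 0.2)
  cv <- mosla_implied_cov(build_mosla_spec(3), p)
  nn <- cv[1:3, 1:3]
  off <- nn[upper.tri(nn)]
  expect_lt(max(abs(off - 0.5)), 1e-14)
  expect_lt(max(abs(diag(nn) - 0.7)), 1e-14)

  # theta -> 0: the covariance goes singular. Six indicators are built from
  # five latents, and N_t - C_t = gN - gC for every wave, so the rank drops
  # to 4 at three waves: two eigenvalues vanish with theta.
  p2 <- mosla_params(0.4, 0.4, 0.1, 0.3, 0.5, theta = 1e-8)
  ev <- sort(eigen(mosla_implied_cov(build_mosla_spec(3), p2),
                   symmetric = TRUE, only.values = TRUE)$values)
  expect_lt(ev[1], 1e-7)
  expect_lt(ev[2], 1e-7)
  expect_gt(ev[3], 1e-4)
})

test_that("fitting the implied covariance recovers generating parameters (waves >= 3)", {
  set.seed(19)
  for (i in 1:10) {
    p <- rand_mosla_params()
    w <- sample(3:4, 1)
    spec <- build_mosla_spec(w)
    fit <- fit_mosla(implied_cov_mosla(p, w), n = 561, spec = spec,
                     compute_se = FALSE)
    expect_lt(fit$F_min, 1e-10)
    expect_lt(max(abs(unlist(fit$theta_hat) - unlist(p))), 1e-4)
    expect_true(fit$converged)
  }
})

test_that("an independence structure fits with vanishing trait covariance and state variance", {
  fit <- fit_mosla(diag(6), n = 561, spec = build_mosla_spec(3),
                   compute_se = FALSE)
  expect_lt(abs(fit$theta_hat$phi_nc), 1e-4)
  expect_lt(fit$theta_hat$psi, 1e-4)
  # moment matching: phi + psi + theta must reproduce the unit diagonal
  expect_equal(fit$theta_hat$phi_n + fit$theta_hat$psi + fit$theta_hat$theta,
               1, tolerance = 1e-4)
})

test_that("fit_mosla validates its input", {
  expect_error(fit_mosla(matrix(c(1, 2, 3, 1), 2), n = 100,
                         spec = build_mosla_spec(3)), "symmetric|rows")
  npd <- diag(6) - 0.5
  expect_error(fit_mosla(npd, n = 100, spec = build_mosla_spec(3)),
               "positive definite")
  expect_error(fit_mosla(diag(6), n = 5, spec = build_mosla_spec(3)),
               "exceed")
})

test_that("sample fits reproduce the analyzed covariance scale and converge", {
  p <- mosla_params()
  d <- simulate_mosla(p, 561, seed = 101)
  S <- cov(unclass(d))
  fit <- fit_mosla(S, n = 561)
  expect_true(fit$converged)
  expect_gte(fit$F_min, 0)
  expect_equal(fit$chi2, 560 * fit$F_min, tolerance = 1e-12)
  expect_identical(fit$df, 15L)
  expect_true(fit$p_value >= 0 && fit$p_value <= 1)
  expect_true(all(is.finite(fit$se)) && all(fit$se > 0))
  # the n-multiplier switch rescales chi2 only
  fit_n <- fit_mosla(S, n = 561, chi2_multiplier = "n", compute_se = FALSE)
  expect_equal(fit_n$chi2 / fit$chi2, 561 / 560, tolerance = 1e-8)
})

test_that("chi-square p-values behave across the domain", {
  expect_equal(chi2_pvalue(0, 7), 1)
  # median of a chi-square tends to its df from below
  expect_equal(chi2_pvalue(1000, 1000), 0.5, tolerance = 0.02)
  expect_lt(chi2_pvalue(30, 10), 0.01)
  expect_error(chi2_pvalue(-1, 5), "chi2")
})

test_that("RMSEA confidence bounds invert the noncentral chi-square correctly", {
  # chi2 far below df: both lambda solutions are negative, bounds clamp to 0
  ci <- rmsea_ci(2, 15, 561)
  expect_identical(unname(ci), c(0, 0))
  # the bound reproduces its defining equation
  ci2 <- rmsea_ci(30, 15, 561)
  lam_u <- ci2["high"]^2 * 15 * 560
  expect_equal(pchisq(30, 15, ncp = lam_u), 0.05, tolerance = 1e-7)
  lam_l <- ci2["low"]^2 * 15 * 560
  expect_equal(pchisq(30, 15, ncp = lam_l), 0.95, tolerance = 1e-7)
  # upper bound strictly increases in chi2
  grid <- seq(5, 60, by = 5)
  highs <- vapply(grid, function(x) rmsea_ci(x, 15, 561)["high"], 0)
  expect_true(all(diff(highs) > 0))
  expect_true(all(vapply(grid, function(x) {
    ci <- rmsea_ci(x, 15, 561); ci["low"] <= ci["high"]
  }, TRUE)))
})

test_that("fit indices hit their boundary identities", {
  p <- mosla_params()
  sig <- implied_cov_mosla(p, 3)
  fit <- fit_mosla(sig, n = 561, spec = build_mosla_spec(3),
                   compute_se = FALSE)
  idx <- fit_indices(fit)
  # saturated-scale fit: chi2 ~ 0 < df
  expect_equal(idx$cfi, 1)
  expect_equal(idx$rmsea, 0)
  expect_gt(idx$tli, 1)  # chi2 < df with a real baseline inflates TLI past 1
  expect_equal(idx$baseline_df, 15)
  expect_gt(idx$baseline_chi2, idx$baseline_df)
})

test_that("the standardized solution obeys its algebraic identities", {
  p <- mosla_params()  # standardized generating values: phi+psi+theta = 1
  fit <- fit_mosla(implied_cov_mosla(p, 3), n = 561,
                   spec = build_mosla_spec(3), compute_se = FALSE)
  std <- standardized_solution(fit)
  gn <- std$estimate[std$parameter == "gN -> MNEE@1"]
  expect_equal(gn, sqrt(p$phi_n), tolerance = 1e-6)
  # variance shares sum to 1 per indicator
  for (v in fit$spec$observed) {
    shares <- std$estimate[grepl(paste0("^", v, ":"), std$parameter)]
    expect_equal(sum(shares), 1, tolerance = 1e-8)
  }
  # sign of the standardized trait correlation matches phi_nc
  tr <- std$estimate[std$parameter == "gN <-> gC"]
  expect_identical(sign(tr), sign(fit$theta_hat$phi_nc))
  # state autoregression standardizes to rho itself under stationarity
  expect_equal(std$estimate[std$parameter == "ST1 -> ST2"],
               fit$theta_hat$rho, tolerance = 1e-10)
})

test_that("reported standard errors track the sampling variability", {
  p <- mosla_params()
  est <- matrix(0, 40, 6); ses <- matrix(0, 40, 6)
  for (i in 1:40) {
    d <- simulate_mosla(p, 561, seed = 400 + i)
    f <- fit_mosla(cov(unclass(d)), 561)
    est[i, ] <- unlist(f$theta_hat); ses[i, ] <- f$se
  }
  ratio <- apply(est, 2, sd) / colMeans(ses)
  expect_true(all(ratio > 0.6 & ratio < 1.6))
})
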