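test_that("equal-precision effects pool to their simple mean under both estimators", {
  yi <- c(0.1, 0.2, 0.3); sei <- rep(0.1, 3)
  for (m in c("REML", "DL")) {
    out <- pool_random_effects(yi = yi, sei = sei, method = m)
    expect_equal(out$estimate, 0.2, tolerance = 1e-10)
    expect_true(out$ci_low <= out$estimate && out$estimate <= out$ci_high)
  }
})

test_that("homogeneous effects give tau2 = Q = I2 = 0 and the common value", {
  yi <- rep(0.15, 6); sei <- rep(0.07, 6)
  for (m in c("REML", "DL")) {
    out <- pool_random_effects(yi = yi, sei = sei, method = m)
    expect_equal(out$estimate, 0.15, tolerance = 1e-12)
    expect_equal(out$tau2, 0, tolerance = 1e-10)
    expect_equal(out$Q, 0, tolerance = 1e-12)
    expect_equal(out$I2, 0)
  }
  # REML and DL agree under exact homogeneity
  r <- pool_random_effects(yi = yi, sei = sei, method = "REML")
  d <- pool_random_effects(yi = yi, sei = sei, method = "DL")
  expect_equal(r$estimate, d$estimate, tolerance = 1e-6)
  expect_equal(r$tau2, d$tau2, tolerance = 1e-6)
})

test_that("DerSimonian-Laird matches brute-force hand arithmetic", {
  yi <- c(0.4, -0.3); sei <- c(0.05, 0.05)
  # hand formula: w = 400 each; Q = w (y1-ybar)^2 + w (y2-ybar)^2
  w <- 1 / sei^2
  ybar <- sum(w * yi) / sum(w)
  Q <- sum(w * (yi - ybar)^2)
  tau2_hand <- max(0, (Q - 1) / (sum(w) - sum(w^2) / sum(w)))
  out <- pool_random_effects(yi = yi, sei = sei, method = "DL")
  expect_equal(out$Q, Q, tolerance = 1e-12)
  expect_equal(out$tau2, tau2_hand, tolerance = 1e-12)
  # two effects, equal se: Q reduces to (y1 - y2)^2 / (2 se^2)
  expect_equal(out$Q, (0.4 - (-0.3))^2 / (2 * 0.05^2), tolerance = 1e-12)
})

test_that("pooling agrees with metafor::rma on random inputs", {
  skip_if_not_installed("metafor")
  set.seed(31)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    yi <- rnorm(k, 0.1, 0.25)
    sei <- runif(k, 0.03, 0.15)
    mine_r <- pool_random_effects(yi = yi, sei = sei, method = "REML")
    ref_r <- metafor::rma(yi = yi, sei = sei, method = "REML",
                          control = list(threshold = 1e-10))
    expect_equal(mine_r$estimate, as.numeric(ref_r$beta), tolerance = 1e-6)
    expect_equal(mine_r$tau2, ref_r$tau2, tolerance = 1e-6)
    expect_equal(mine_r$se, ref_r$se, tolerance = 1e-6)
    mine_d <- pool_random_effects(yi = yi, sei = sei, method = "DL")
    ref_d <- metafor::rma(yi = yi, sei = sei, method = "DL")
    expect_equal(mine_d$tau2, ref_d$tau2, tolerance = 1e-10)
    expect_equal(mine_d$Q, ref_d$QE, tolerance = 1e-10)
  }
})

test_that("heterogeneity is permutation invariant and I2 is clamped", {
  yi <- c(0.1, 0.5, -0.2, 0.3); sei <- c(0.05, 0.1, 0.07, 0.2)
  h1 <- heterogeneity(yi, sei)
  perm <- c(3, 1, 4, 2)
  h2 <- heterogeneity(yi[perm], sei[perm])
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_true(h1["I2"] >= 0 && h1["I2"] <= 100)
  # nearly identical effects: Q < k-1 so I2 clamps to 0
  h3 <- heterogeneity(c(0.2, 0.2001, 0.1999), rep(0.1, 3))
  expect_equal(unname(h3["I2"]), 0)
})

test_that("tau2 boundaries recover the fixed-effect and unweighted limits", {
  yi <- c(0.05, 0.3, 0.6); sei <- c(0.02, 0.1, 0.3)
  w_fe <- 1 / sei^2
  fe <- sum(w_fe * yi) / sum(w_fe)
  # homogeneous-looking data so REML hits the tau2 = 0 boundary
  out0 <- pool_random_effects(yi = c(0.2, 0.2, 0.2), sei = sei)
  expect_equal(out0$tau2, 0, tolerance = 1e-10)
  w0 <- 1 / sei^2
  expect_equal(out0$estimate, sum(w0 * 0.2) / sum(w0), tolerance = 1e-10)
  # a huge injected tau2 drives the pooled value to the unweighted mean
  tau2_big <- 1e6
  w_big <- 1 / (sei^2 + tau2_big)
  est_big <- sum(w_big * yi) / sum(w_big)
  expect_equal(est_big, mean(yi), tolerance = 1e-4)
})

test_that("pooling validates its input", {
  expect_error(pool_random_effects(yi = 0.2, sei = 0.1), "at least 2")
  expect_error(pool_random_effects(yi = c(0.1, NA), sei = c(0.1, 0.1)),
               "finite")
  expect_error(pool_random_effects(yi = c(0.1, 0.2), sei = c(0.1, 0)),
               "positive")
})

test_that("a panel of sign-straddling effects can pool to a null CI", {
  # both timeframes built from the sign-flip triple
  r <- triple_worked()
  tgt <- make_study_corr()
  # construct a 561-subject exact dataset whose (X1, Y1, Y2) triple is the
  # worked one for both timeframes, symmetrically
  labels <- c("X@1", "X@2", "Y@1", "Y@2", "Y@3")
  m <- diag(5)
  dimnames(m) <- list(labels, labels)
  m["X@1", "Y@1"] <- m["Y@1", "X@1"] <- r$r_x1y1
  m["X@1", "Y@2"] <- m["Y@2", "X@1"] <- r$r_x1y2
  m["Y@1", "Y@2"] <- m["Y@2", "Y@1"] <- r$r_y1y2
  m["X@2", "Y@2"] <- m["Y@2", "X@2"] <- r$r_x1y1
  m["X@2", "Y@3"] <- m["Y@3", "X@2"] <- r$r_x1y2
  m["Y@2", "Y@3"] <- m["Y@3", "Y@2"] <- r$r_y1y2
  m["X@1", "X@2"] <- m["X@2", "X@1"] <- 0.5
  m["Y@1", "Y@3"] <- m["Y@3", "Y@1"] <- 0.3
  tgt <- long_corr(m)
  d <- simulate_from_corr(tgt, n = 561, seed = 23)
  ests <- list(
    fit_difference_model(d, "X@1", c("Y@1", "Y@2"), "adjust_initial"),
    fit_difference_model(d, "X@2", c("Y@2", "Y@3"), "adjust_initial"),
    fit_difference_model(d, "X@1", c("Y@1", "Y@2"), "adjust_subsequent"),
    fit_difference_model(d, "X@2", c("Y@2", "Y@3"), "adjust_subsequent"),
    fit_difference_model(d, "X@1", c("Y@1", "Y@2"), "unadjusted"),
    fit_difference_model(d, "X@2", c("Y@2", "Y@3"), "unadjusted")
  )
  coefs <- vapply(ests, `[[`, 0, "coefficient")
  expect_gt(max(coefs), 0)   # a1 effects positive
  expect_lt(min(coefs), 0)   # b1 effects negative
  pooled <- pool_random_effects(ests)
  expect_true(pooled$ci_low < 0 && pooled$ci_high > 0)
})
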