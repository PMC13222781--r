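# Maximum-likelihood structural-equation engine for the Model of Spurious
# Longitudinal Associations (MoSLA): observed scores on two constructs load
# (with unit loadings) on stable trait factors and on shared, autocorrelated
# occasion-state factors; there are no direct effects among observed scores.
#
# For W waves the model has exactly six free parameters: the two trait
# variances, their covariance, the stationary state variance, the state
# autocorrelation, and one residual variance shared by all indicators.
# With W = 3 this gives 21 nonredundant moments - 6 parameters = 15 df.

#' Build a MoSLA model specification
#'
#' Constructs the path-model layout for a given number of waves: observed
#' variables (two constructs x waves), latent variables (two traits `gN`,
#' `gC` and one state factor `ST_t` per wave), all loadings fixed at 1, the
#' state process stationary AR(1), a single residual variance shared by all
#' indicators, and free parameters
#' `phi_n, phi_c, phi_nc, psi, rho, theta`.
#'
#' @param waves number of measurement waves (>= 2).
#' @param constructs length-2 character vector of construct names.
#' @return An object of class `mosla_spec` with elements `waves`,
#'   `constructs`, `observed`, `latent`, `free`, `n_moments`, `df`.
#' @examples
#' build_mosla_spec(3)$df  # 15
#' @export
build_mosla_spec <- function(waves = 3, constructs = c("MNEE", "CU")) {
  waves <- as.integer(waves)
  if (waves < 2L) stop("waves must be >= 2")
  if (length(constructs) != 2L) stop("exactly two constructs")
  observed <- c(panel_label(constructs[1L], seq_len(waves)),
                panel_label(constructs[2L], seq_len(waves)))
  latent <- c("gN", "gC", paste0("ST", seq_len(waves)))
  p <- length(observed)
  free <- c("phi_n", "phi_c", "phi_nc", "psi", "rho", "theta")
  moments <- (p * (p + 1L)) %/% 2L
  structure(list(
    waves = waves, constructs = constructs,
    observed = observed, latent = latent, free = free,
    n_moments = moments,
    df = moments - length(free)
  ), class = "mosla_spec")
}

#' @export
print.mosla_spec <- function(x, ...) {
  cat("MoSLA specification: ", x$waves, " waves, observed = {",
      paste(x$observed, collapse = ", "), "}\n", sep = "")
  cat("  latent = {", paste(x$latent, collapse = ", "), "}; ",
      length(x$free), " free parameters; df = ", x$df, "\n", sep = "")
  invisible(x)
}

# RAM matrices (A: directed paths, S: exogenous covariances, F: filter)
ram_matrices <- function(spec, params) {
  w <- spec$waves
  p <- 2L * w
  m <- p + w + 2L
  vars <- c(spec$observed, spec$latent)
  A <- matrix(0, m, m, dimnames = list(vars, vars))
  S <- matrix(0, m, m, dimnames = list(vars, vars))
  for (t in seq_len(w)) {
    A[t, "gN"] <- 1                       # N_t <- gN
    A[w + t, "gC"] <- 1                   # C_t <- gC
    A[t, paste0("ST", t)] <- 1            # N_t <- ST_t
    A[w + t, paste0("ST", t)] <- 1        # C_t <- ST_t
    if (t > 1L) A[paste0("ST", t), paste0("ST", t - 1L)] <- params$rho
  }
  S["gN", "gN"] <- params$phi_n
  S["gC", "gC"] <- params$phi_c
  S["gN", "gC"] <- S["gC", "gN"] <- params$phi_nc
  S["ST1", "ST1"] <- params$psi
  if (w > 1L) {
    dvar <- params$psi * (1 - params$rho^2)  # stationarity by construction
    for (t in 2:w) S[paste0("ST", t), paste0("ST", t)] <- dvar
  }
  diag(S)[seq_len(p)] <- params$theta
  Fm <- cbind(diag(p), matrix(0, p, w + 2L))
  dimnames(Fm) <- list(spec$observed, vars)
  list(A = A, S = S, F = Fm)
}

#' Model-implied covariance via the RAM path formula
#'
#' Evaluates `Sigma = F (I - A)^{-1} S (I - A)^{-T} F^T`, the reticular
#' action model expression over the directed-path matrix `A`, the exogenous
#' covariance matrix `S` and the observed-variable filter `F`. This is an
#' independent derivation of the same matrix as the closed form in
#' [implied_cov_mosla()]; the two agree to machine precision.
#'
#' @param spec a [build_mosla_spec()] object.
#' @param params a [mosla_params] object.
#' @return Labeled covariance matrix over the observed variables.
#' @export
mosla_implied_cov <- function(spec, params) {
  stopifnot(inherits(spec, "mosla_spec"), inherits(params, "mosla_params"))
  ram <- ram_matrices(spec, params)
  inv <- solve(diag(nrow(ram$A)) - ram$A)
  sigma <- ram$F %*% inv %*% ram$S %*% t(inv) %*% t(ram$F)
  dimnames(sigma) <- list(spec$observed, spec$observed)
  (sigma + t(sigma)) / 2
}

# ---- parameter transforms ---------------------------------------------------
# Unconstrained optimization space: log-variances, atanh trait correlation,
# atanh state autocorrelation.

params_to_x <- function(params) {
  r <- params$phi_nc / sqrt(params$phi_n * params$phi_c)
  c(log(params$phi_n), log(params$phi_c), atanh(max(-1 + 1e-12,
                                                    min(1 - 1e-12, r))),
    log(max(params$psi, 1e-12)), atanh(params$rho), log(params$theta))
}

x_to_params <- function(x) {
  phi_n <- exp(x[1L]); phi_c <- exp(x[2L])
  list(phi_n = phi_n, phi_c = phi_c,
       phi_nc = tanh(x[3L]) * sqrt(phi_n * phi_c),
       psi = exp(x[4L]), rho = tanh(x[5L]), theta = exp(x[6L]))
}

x_to_vec <- function(x) unlist(x_to_params(x))

# ---- discrepancy ------------------------------------------------------------

fml_discrepancy <- function(sigma, S, log_det_S) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  log_det_sigma <- 2 * sum(log(diag(ch)))
  f <- log_det_sigma + sum(diag(chol2inv(ch) %*% S)) - log_det_S - ncol(S)
  if (!is.finite(f)) return(1e10)
  f
}

# moment-based starting values from the average lag structure of S
moment_start <- function(S, waves) {
  w <- waves
  N <- seq_len(w); C <- w + N
  lag_mean <- function(block_r, block_c, lag) {
    vals <- c()
    for (t in seq_len(w)) for (u in seq_len(w)) {
      if (abs(t - u) == lag) vals <- c(vals, S[block_r[t], block_c[u]])
    }
    mean(vals)
  }
  cr0 <- lag_mean(N, C, 0); cr1 <- lag_mean(N, C, 1)
  cr2 <- if (w >= 3) lag_mean(N, C, 2) else NA_real_
  d1 <- cr0 - cr1
  rho0 <- if (!is.na(cr2) && abs(d1) > 1e-8) (cr1 - cr2) / d1 else 0.3
  rho0 <- max(-0.9, min(0.9, rho0))
  psi0 <- if (abs(1 - rho0) > 1e-8) d1 / (1 - rho0) else 0.2
  psi0 <- max(psi0, 0.01)
  phi_nc0 <- cr0 - psi0
  phi_n0 <- max(lag_mean(N, N, 1) - psi0 * rho0, 0.05)
  phi_c0 <- max(lag_mean(C, C, 1) - psi0 * rho0, 0.05)
  theta0 <- max(mean(diag(S)[c(N, C)]) - mean(c(phi_n0, phi_c0)) - psi0, 0.05)
  bound <- sqrt(phi_n0 * phi_c0)
  phi_nc0 <- max(-0.95 * bound, min(0.95 * bound, phi_nc0))
  mosla_params(phi_n0, phi_c0, phi_nc0, psi0, rho0, theta0)
}

#' Fit the MoSLA by maximum likelihood
#'
#' Minimizes the normal-theory ML discrepancy
#' `F_ML = log|Sigma| + tr(S Sigma^-1) - log|S| - p`
#' over an unconstrained reparameterization (log-variances,
#' hyperbolic-tangent-transformed correlations) using a quasi-Newton search
#' from moment-based starting values, followed by damped Newton polishing of
#' the gradient to max-norm below `1e-8`. Random restarts from perturbed
#' starts are used if the first search fails to converge. Standard errors
#' come from the inverse numerical Hessian of `(mult/2) F_ML` at the
#' optimum, mapped through the transformation Jacobian (delta method).
#'
#' @param S sample covariance (or correlation) matrix of the observed
#'   variables, symmetric positive definite. May be a labeled matrix (e.g.
#'   a [long_corr]); columns are matched to the spec's observed order.
#' @param n sample size the covariance was computed from.
#' @param spec a [build_mosla_spec()] object; by default inferred from the
#'   labels of `S` (or 3 waves).
#' @param chi2_multiplier `"nm1"` for the Wishart convention
#'   `chi2 = (n-1) F_min` (default) or `"n"`.
#' @param restarts maximum number of perturbed restarts (default 5).
#' @param seed integer seed controlling restart perturbations.
#' @param compute_se logical; skip to speed up Monte-Carlo sweeps.
#' @param grad_tol convergence criterion on the gradient max-norm.
#' @return An object of class `mosla_fit`: estimated [mosla_params], their
#'   standard errors, `F_min`, `chi2`, `df`, `p_value`, convergence
#'   diagnostics, plus the analyzed `S` and `n`.
#' @export
fit_mosla <- function(S, n, spec = NULL, chi2_multiplier = c("nm1", "n"),
                      restarts = 5L, seed = 1L, compute_se = TRUE,
                      grad_tol = 1e-8) {
  chi2_multiplier <- match.arg(chi2_multiplier)
  S <- as.matrix(S)
  if (is.null(spec)) {
    if (!is.null(colnames(S))) {
      info <- parse_panel_labels(colnames(S))
      constructs <- unique(info$construct)
      if (length(constructs) != 2L) stop("S must cover exactly two constructs")
      spec <- build_mosla_spec(max(info$wave), constructs)
    } else {
      spec <- build_mosla_spec(nrow(S) / 2L)
    }
  }
  p <- length(spec$observed)
  if (!is.null(colnames(S))) {
    missing <- setdiff(spec$observed, colnames(S))
    if (length(missing)) stop("S lacks variable(s): ",
                              paste(missing, collapse = ", "))
    S <- S[spec$observed, spec$observed]
  } else if (nrow(S) != p) {
    stop("S has ", nrow(S), " rows but the spec expects ", p)
  }
  if (max(abs(S - t(S))) > 1e-10) stop("S must be symmetric")
  S <- (S + t(S)) / 2
  if (n <= p) stop("n must exceed the number of observed variables")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("S must be positive definite")
  log_det_S <- sum(log(ev))

  fml <- function(x) {
    pars <- x_to_params(x)
    if (any(!is.finite(unlist(pars)))) return(1e10)
    fml_discrepancy(mosla_implied_cov(spec, structure(pars,
                                                      class = "mosla_params")),
                    S, log_det_S)
  }
  gr <- function(x) pracma::grad(fml, x)

  newton_polish <- function(x, maxsteps = 30L) {
    f <- fml(x)
    for (i in seq_len(maxsteps)) {
      g <- gr(x)
      if (max(abs(g)) < grad_tol) break
      H <- pracma::hessian(fml, x)
      step <- tryCatch(-solve(H + diag(1e-10, length(x)), g),
                       error = function(e) -g)
      lam <- 1
      repeat {
        f_new <- fml(x + lam * step)
        if (f_new <= f + 1e-14) break
        lam <- lam / 2
        if (lam < 1e-10) break
      }
      if (fml(x + lam * step) > f + 1e-14) break
      x <- x + lam * step
      f <- fml(x)
    }
    list(x = x, f = f, g = gr(x))
  }

  run_from <- function(x0) {
    opt <- stats::nlminb(x0, fml, gradient = gr,
                         control = list(eval.max = 2000L, iter.max = 1000L,
                                        rel.tol = 1e-14, x.tol = 1e-14))
    newton_polish(opt$par)
  }

  start <- params_to_x(moment_start(S, spec$waves))
  best <- run_from(start)
  attempt <- 0L
  while (max(abs(best$g)) > grad_tol && attempt < restarts) {
    attempt <- attempt + 1L
    x0 <- start + with_local_seed(substream_seed(seed, attempt),
                                  stats::rnorm(length(start), sd = 0.3))
    cand <- run_from(x0)
    if (cand$f < best$f - 1e-14 ||
        (max(abs(cand$g)) < max(abs(best$g)))) best <- cand
  }
  grad_norm <- max(abs(best$g))
  converged <- grad_norm < grad_tol
  if (grad_norm > 1e-5) {
    stop("ML optimization failed to converge after ", restarts,
         " restarts: F_min = ", format(best$f),
         ", gradient max-norm = ", format(grad_norm))
  }
  if (!converged) {
    warning("gradient max-norm ", format(grad_norm),
            " above tolerance; estimates may be slightly unpolished")
  }

  xhat <- best$x
  pars <- x_to_params(xhat)
  theta_hat <- mosla_params(pars$phi_n, pars$phi_c, pars$phi_nc,
                            pars$psi, pars$rho, pars$theta)
  mult <- if (chi2_multiplier == "nm1") n - 1 else n
  F_min <- max(best$f, 0)
  chi2 <- mult * F_min
  df <- spec$df

  se <- rep(NA_real_, 6L)
  names(se) <- spec$free
  if (compute_se) {
    H <- pracma::hessian(function(x) 0.5 * mult * fml(x), xhat)
    cov_x <- tryCatch(solve(H), error = function(e) pracma::pinv(H))
    J <- pracma::jacobian(x_to_vec, xhat)
    cov_theta <- J %*% cov_x %*% t(J)
    se <- sqrt(pmax(diag(cov_theta), 0))
    names(se) <- spec$free
  }

  structure(list(
    theta_hat = theta_hat, se = se, S = S, n = n, spec = spec,
    F_min = F_min, chi2 = chi2, df = df,
    p_value = chi2_pvalue(chi2, df),
    chi2_multiplier = chi2_multiplier,
    converged = converged, grad_norm = grad_norm, x_hat = xhat
  ), class = "mosla_fit")
}

#' @export
print.mosla_fit <- function(x, ...) {
  cat("MoSLA maximum-likelihood fit (n =", x$n, ")\n")
  est <- unlist(x$theta_hat)
  tab <- data.frame(estimate = est, se = x$se[names(est)])
  print(round(tab, 4))
  cat(sprintf("chi2 = %.3f, df = %d, p = %.3f (F_min = %.3g, %s multiplier)\n",
              x$chi2, x$df, x$p_value, x$F_min,
              if (x$chi2_multiplier == "nm1") "n-1" else "n"))
  invisible(x)
}

# ---- fit statistics ---------------------------------------------------------

#' Upper-tail chi-square probability
#'
#' @param chi2 test statistic (>= 0).
#' @param df degrees of freedom (>= 1).
#' @return The upper-tail probability of the central chi-square distribution.
#' @export
chi2_pvalue <- function(chi2, df) {
  if (chi2 < 0 || df < 1) stop("require chi2 >= 0 and df >= 1")
  stats::pchisq(chi2, df, lower.tail = FALSE)
}

#' RMSEA confidence interval by noncentral chi-square inversion
#'
#' The lower bound uses the noncentrality `lambda_L` solving
#' `P(chisq(df, lambda) <= chi2) = 1 - (1-level)/2` and the upper bound
#' `lambda_U` solving `P(chisq(df, lambda) <= chi2) = (1-level)/2`; a
#' lambda with no nonnegative solution is set to 0. Each bound is
#' `sqrt(lambda / (df (n-1)))`.
#'
#' @param chi2 test statistic.
#' @param df model degrees of freedom.
#' @param n sample size.
#' @param level confidence level (default 0.90, the SEM convention).
#' @return Named numeric vector `c(low, high)`.
#' @export
rmsea_ci <- function(chi2, df, n, level = 0.90) {
  if (chi2 < 0) stop("chi2 must be nonnegative")
  alpha <- (1 - level) / 2
  solve_ncp <- function(target) {
    f <- function(l) stats::pchisq(chi2, df, ncp = l) - target
    if (f(0) < 0) return(0)  # no nonnegative solution
    hi <- 10 * df * n
    if (f(hi) > 0) stop("noncentrality bracketing failed: f(", hi, ") = ",
                        format(f(hi)), " for target ", target)
    stats::uniroot(f, c(0, hi), tol = 1e-10)$root
  }
  lam_l <- solve_ncp(1 - alpha)
  lam_u <- solve_ncp(alpha)
  c(low = sqrt(lam_l / (df * (n - 1))), high = sqrt(lam_u / (df * (n - 1))))
}

#' Fit indices for a MoSLA fit
#'
#' CFI and TLI against the independence baseline (all covariances zero,
#' variances free, `baseline_df = p(p-1)/2`), the RMSEA point estimate
#' `sqrt(max(chi2 - df, 0) / (df (n-1)))`, and its noncentral chi-square
#' confidence interval. When the baseline is no better defined than the
#' model (denominator <= 0) the affected index is `NA`, not fabricated.
#'
#' @param fit a [fit_mosla()] result.
#' @param level RMSEA confidence level (default 0.90).
#' @return An object of class `fit_indices`: `chi2`, `df`, `p_value`,
#'   `cfi`, `tli`, `rmsea`, `rmsea_ci_low`, `rmsea_ci_high`,
#'   `baseline_chi2`, `baseline_df`.
#' @export
fit_indices <- function(fit, level = 0.90) {
  stopifnot(inherits(fit, "mosla_fit"))
  S <- fit$S
  p <- ncol(S)
  mult <- if (fit$chi2_multiplier == "nm1") fit$n - 1 else fit$n
  # independence baseline: diagonal Sigma with MLE variances diag(S)
  F_base <- sum(log(diag(S))) - determinant(S, logarithm = TRUE)$modulus[1]
  baseline_chi2 <- mult * max(F_base, 0)
  baseline_df <- p * (p - 1) / 2
  d_model <- max(fit$chi2 - fit$df, 0)
  d_base <- baseline_chi2 - baseline_df
  denom <- max(d_base, fit$chi2 - fit$df, 0)
  cfi <- if (denom > 0) 1 - d_model / denom else if (d_model == 0) 1 else NA_real_
  rb <- baseline_chi2 / baseline_df
  tli <- if (abs(rb - 1) > 1e-12) {
    (rb - fit$chi2 / fit$df) / (rb - 1)
  } else NA_real_
  rmsea <- sqrt(max(fit$chi2 - fit$df, 0) / (fit$df * (fit$n - 1)))
  ci <- rmsea_ci(fit$chi2, fit$df, fit$n, level = level)
  structure(list(
    chi2 = fit$chi2, df = fit$df, p_value = fit$p_value,
    cfi = cfi, tli = tli, rmsea = rmsea,
    rmsea_ci_low = unname(ci["low"]), rmsea_ci_high = unname(ci["high"]),
    rmsea_ci_level = level,
    baseline_chi2 = baseline_chi2, baseline_df = baseline_df
  ), class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf(
    "chi2 = %.3f, df = %d, p = %.3f, CFI = %.3f, TLI = %.3f, RMSEA = %.3f [%d%% CI: %.3f; %.3f]\n",
    x$chi2, x$df, x$p_value, x$cfi, x$tli, x$rmsea,
    round(100 * x$rmsea_ci_level), x$rmsea_ci_low, x$rmsea_ci_high))
  invisible(x)
}

#' Standardized solution of a MoSLA fit
#'
#' Rescales each path/loading by the ratio of the implied standard
#' deviations of its source and target variables, reports the trait
#' covariance as a correlation, and decomposes each indicator's implied
#' variance into trait, state and residual proportions (which sum to 1).
#'
#' @param fit a converged [fit_mosla()] result.
#' @return A data frame with columns `parameter`, `type`, `estimate`.
#' @export
standardized_solution <- function(fit) {
  stopifnot(inherits(fit, "mosla_fit"))
  pars <- fit$theta_hat
  spec <- fit$spec
  sigma <- mosla_implied_cov(spec, pars)
  sds <- sqrt(diag(sigma))
  if (any(sds <= 0)) stop("zero implied variance; standardization undefined")
  w <- spec$waves
  rows <- list()
  add <- function(parameter, type, estimate) {
    rows[[length(rows) + 1L]] <<- data.frame(parameter = parameter,
                                             type = type,
                                             estimate = estimate,
                                             stringsAsFactors = FALSE)
  }
  sd_st <- sqrt(pars$psi)
  for (t in seq_len(w)) {
    vN <- spec$observed[t]; vC <- spec$observed[w + t]
    add(paste0("gN -> ", vN), "loading", sqrt(pars$phi_n) / sds[vN])
    add(paste0("gC -> ", vC), "loading", sqrt(pars$phi_c) / sds[vC])
    add(paste0("ST", t, " -> ", vN), "loading", sd_st / sds[vN])
    add(paste0("ST", t, " -> ", vC), "loading", sd_st / sds[vC])
    if (t > 1L) add(paste0("ST", t - 1L, " -> ST", t), "regression", pars$rho)
  }
  add("gN <-> gC", "correlation",
      pars$phi_nc / sqrt(pars$phi_n * pars$phi_c))
  for (v in spec$observed) {
    tot <- sigma[v, v]
    trait_var <- if (match(v, spec$observed) <= w) pars$phi_n else pars$phi_c
    add(paste0(v, ": trait share"), "variance", trait_var / tot)
    add(paste0(v, ": state share"), "variance", pars$psi / tot)
    add(paste0(v, ": residual share"), "variance", pars$theta / tot)
  }
  do.call(rbind, rows)
}
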