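# Synthetic panel-data generators: MoSLA process, exact/sampled draws from a
# target correlation matrix, and a common-cause model without a direct
# cross-lagged path.

#' Parameters of the trait-state generating process (MoSLA)
#'
#' The Model of Spurious Longitudinal Associations generates observed scores
#' on two constructs as trait + shared occasion state + residual:
#' \deqn{N_t = gN + ST_t + e_{Nt}, \qquad C_t = gC + ST_t + e_{Ct}}
#' with traits \eqn{(gN, gC)} bivariate normal (variances `phi_n`, `phi_c`,
#' covariance `phi_nc`), a single occasion-state factor per wave shared by
#' both constructs following a stationary AR(1) process with variance `psi`
#' and autocorrelation `rho`, and iid residuals with variance `theta`.
#' There are no direct effects among observed scores.
#'
#' The defaults describe a standardized process (total variance
#' `phi + psi + theta = 1` per construct), the regime in which observed
#' scores are on a correlation scale.
#'
#' @param phi_n,phi_c trait variances (> 0).
#' @param phi_nc trait covariance; `|phi_nc| <= sqrt(phi_n * phi_c)`.
#' @param psi stationary occasion-state variance (>= 0).
#' @param rho state autocorrelation, `|rho| < 1`.
#' @param theta residual variance (> 0), shared by all indicators.
#' @return An object of class `mosla_params` (named list).
#' @export
mosla_params <- function(phi_n = 0.4, phi_c = 0.4, phi_nc = 0.1,
                         psi = 0.3, rho = 0.5, theta = 0.3) {
  p <- list(phi_n = phi_n, phi_c = phi_c, phi_nc = phi_nc,
            psi = psi, rho = rho, theta = theta)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v), TRUE))) {
    stop("all MoSLA parameters must be finite scalars")
  }
  if (phi_n <= 0 || phi_c <= 0) stop("trait variances must be positive")
  if (psi < 0) stop("state variance psi must be nonnegative")
  if (theta <= 0) stop("residual variance theta must be positive")
  if (abs(rho) >= 1) stop("state autocorrelation rho must satisfy |rho| < 1")
  if (abs(phi_nc) > sqrt(phi_n * phi_c) + 1e-12) {
    stop("trait covariance exceeds Cauchy-Schwarz bound")
  }
  structure(p, class = "mosla_params")
}

#' @export
print.mosla_params <- function(x, ...) {
  cat("MoSLA parameters: phi_N =", x$phi_n, " phi_C =", x$phi_c,
      " phi_NC =", x$phi_nc, "\n  psi =", x$psi, " rho =", x$rho,
      " theta =", x$theta, "\n")
  tot <- c(x$phi_n, x$phi_c) + x$psi + x$theta
  cat("  implied total variances:", paste(round(tot, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Closed-form covariance implied by the MoSLA
#'
#' Evaluates the model-implied covariance directly from the process
#' definition:
#' \deqn{cov(N_t, N_u) = \phi_N + \psi\rho^{|t-u|} + [t=u]\,\theta}
#' and analogously for the second construct, with
#' \eqn{cov(N_t, C_u) = \phi_{NC} + \psi\rho^{|t-u|}}. This is one of two
#' independent derivations of the same matrix; the other is the RAM path
#' formula in [mosla_implied_cov()].
#'
#' @param params a [mosla_params] object.
#' @param waves number of measurement waves (>= 2).
#' @param constructs length-2 character vector of construct names.
#' @return A labeled symmetric covariance matrix (construct-major column
#'   order: first construct waves 1..W, then second).
#' @export
implied_cov_mosla <- function(params, waves = 3,
                              constructs = c("MNEE", "CU")) {
  stopifnot(inherits(params, "mosla_params"))
  waves <- as.integer(waves)
  if (waves < 2L) stop("waves must be >= 2")
  if (length(constructs) != 2L) stop("exactly two constructs")
  labels <- c(panel_label(constructs[1L], seq_len(waves)),
              panel_label(constructs[2L], seq_len(waves)))
  p <- 2L * waves
  idx_con <- rep(1:2, each = waves)
  idx_wave <- rep(seq_len(waves), 2L)
  phi <- matrix(c(params$phi_n, params$phi_nc, params$phi_nc, params$phi_c), 2)
  out <- matrix(0, p, p, dimnames = list(labels, labels))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      lag <- abs(idx_wave[i] - idx_wave[j])
      out[i, j] <- phi[idx_con[i], idx_con[j]] + params$psi * params$rho^lag +
        (i == j) * params$theta
    }
  }
  out
}

#' Simulate panel data from the MoSLA process
#'
#' Draws traits from a bivariate normal, builds the shared occasion-state
#' sequence as a stationary AR(1) (`ST_1 ~ N(0, psi)`,
#' `ST_t = rho ST_{t-1} + d_t`, `var(d_t) = psi (1 - rho^2)`), adds iid
#' residuals, and returns observed = trait + state + residual. Traits, each
#' wave's state disturbance, and each wave's residuals use deterministic RNG
#' sub-streams derived from `seed`, so increasing `waves` does not perturb
#' earlier draws.
#'
#' @inheritParams implied_cov_mosla
#' @param n number of subjects (>= 10).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return A [panel_data] object (not standardized).
#' @export
simulate_mosla <- function(params, n = 561, waves = 3, seed = 1,
                           constructs = c("MNEE", "CU")) {
  stopifnot(inherits(params, "mosla_params"))
  n <- as.integer(n)
  waves <- as.integer(waves)
  if (n < 10L) stop("n must be >= 10")
  if (waves < 2L) stop("waves must be >= 2")

  # traits: stream 0
  phi <- matrix(c(params$phi_n, params$phi_nc, params$phi_nc, params$phi_c), 2)
  traits <- with_local_seed(substream_seed(seed, 0L),
                            MASS::mvrnorm(n, mu = c(0, 0), Sigma = phi))

  # shared states: stream per wave
  st <- matrix(0, n, waves)
  st[, 1L] <- with_local_seed(substream_seed(seed, 1L),
                              stats::rnorm(n, sd = sqrt(params$psi)))
  if (waves > 1L) {
    dvar <- params$psi * (1 - params$rho^2)
    for (t in 2:waves) {
      d <- with_local_seed(substream_seed(seed, t),
                           stats::rnorm(n, sd = sqrt(dvar)))
      st[, t] <- params$rho * st[, t - 1L] + d
    }
  }

  # residuals: stream per wave (both constructs at a wave drawn together)
  obs <- matrix(0, n, 2L * waves)
  for (t in seq_len(waves)) {
    e <- with_local_seed(substream_seed(seed, 1000L + t),
                         matrix(stats::rnorm(2L * n, sd = sqrt(params$theta)),
                                n, 2L))
    obs[, t] <- traits[, 1L] + st[, t] + e[, 1L]
    obs[, waves + t] <- traits[, 2L] + st[, t] + e[, 2L]
  }
  colnames(obs) <- c(panel_label(constructs[1L], seq_len(waves)),
                     panel_label(constructs[2L], seq_len(waves)))
  panel_data(obs)
}

# symmetric matrix square root (and inverse square root) via eigen
sqrtm_sym <- function(m, inverse = FALSE, tol = 1e-12) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- e$values
  if (inverse && any(vals < tol * max(vals))) {
    stop("matrix is numerically singular; cannot whiten")
  }
  vals <- pmax(vals, 0)
  half <- if (inverse) 1 / sqrt(vals) else sqrt(vals)
  e$vectors %*% (half * t(e$vectors))
}

#' Simulate panel data matching a target correlation matrix
#'
#' With `exact = TRUE` (the default) the returned data's empirical
#' correlation matrix (population divisor) equals `target` to machine
#' precision: iid normal deviates are column-centered, whitened by the
#' inverse symmetric square root of their sample covariance, then colored by
#' the symmetric square root of the target. Symmetric square roots avoid any
#' dependence on variable ordering. With `exact = FALSE` the rows are draws
#' from a multivariate normal whose population correlation is `target`, then
#' standardized.
#'
#' Exact mode makes correlation-driven closed forms and regression estimates
#' coincide: standardized regression effects are functions of correlations
#' only.
#'
#' @param target a [long_corr] (or labeled PSD correlation matrix).
#' @param n number of subjects; must exceed the number of variables in exact
#'   mode.
#' @param seed integer seed.
#' @param exact logical; reproduce `target` exactly in the sample.
#' @return A standardized [panel_data] object.
#' @export
simulate_from_corr <- function(target, n = 561, seed = 1, exact = TRUE) {
  if (!inherits(target, "long_corr")) target <- long_corr(target)
  p <- ncol(target)
  n <- as.integer(n)
  if (n <= p) stop("n must exceed the number of variables")
  if (exact) {
    x <- with_local_seed(seed, matrix(stats::rnorm(n * p), n, p))
    xc <- sweep(x, 2L, colMeans(x))
    cx <- crossprod(xc) / n
    if (min(eigen(cx, symmetric = TRUE, only.values = TRUE)$values) <
        1e-10) {
      stop("rank-deficient deviate matrix; increase n")
    }
    z <- xc %*% sqrtm_sym(cx, inverse = TRUE)   # empirical cov exactly I
    y <- z %*% sqrtm_sym(unclass(target))       # empirical cov exactly target
    colnames(y) <- colnames(target)
    panel_data(y, standardized = TRUE)
  } else {
    y <- with_local_seed(seed,
                         MASS::mvrnorm(n, mu = rep(0, p),
                                       Sigma = unclass(target)))
    colnames(y) <- colnames(target)
    standardize_panel(y)
  }
}

# ---- common-cause model -----------------------------------------------------

#' Common-cause generating model with no direct cross-lagged path
#'
#' Standardized three-variable model: a latent common cause CC loads on X1,
#' Y1 and Y2; Y2 additionally regresses on Y1; there is no X1 -> Y2 path.
#' Unique variances are implied so that every observed variable has unit
#' variance. Data generated this way produce a nonzero cross-lagged effect
#' of X1 on Y2 adjusting for Y1 even though X1 has no direct effect —
#' the textbook uncertainty of the cross-lagged panel model.
#'
#' @param load_cc_x1,load_cc_y1,load_cc_y2 standardized loadings of CC.
#' @param auto_y1_y2 standardized direct path Y1 -> Y2.
#' @return An object of class `common_cause_spec`.
#' @export
common_cause_spec <- function(load_cc_x1, load_cc_y1, load_cc_y2,
                              auto_y1_y2 = 0) {
  s <- list(load_cc_x1 = load_cc_x1, load_cc_y1 = load_cc_y1,
            load_cc_y2 = load_cc_y2, auto_y1_y2 = auto_y1_y2)
  if (!all(vapply(s, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v), TRUE))) {
    stop("all loadings/paths must be finite scalars")
  }
  u_x1 <- 1 - load_cc_x1^2
  u_y1 <- 1 - load_cc_y1^2
  u_y2 <- 1 - (load_cc_y2^2 + auto_y1_y2^2 +
                 2 * auto_y1_y2 * load_cc_y1 * load_cc_y2)
  if (min(u_x1, u_y1, u_y2) < -1e-12) {
    stop("implied unique variance negative; loadings/path too large for ",
         "unit observed variances")
  }
  s$unique <- c(x1 = max(u_x1, 0), y1 = max(u_y1, 0), y2 = max(u_y2, 0))
  r <- implied_corr_common_cause_(s)
  if (max(abs(r)) > 1 + 1e-12) stop("implied correlation exceeds 1")
  structure(s, class = "common_cause_spec")
}

implied_corr_common_cause_ <- function(s) {
  c(r_x1y1 = s$load_cc_x1 * s$load_cc_y1,
    r_x1y2 = s$load_cc_x1 * (s$load_cc_y2 + s$auto_y1_y2 * s$load_cc_y1),
    r_y1y2 = s$load_cc_y1 * s$load_cc_y2 + s$auto_y1_y2)
}

#' Correlations implied by a common-cause specification
#'
#' Path-tracing on the standardized model:
#' `r_x1y1 = l_x1 l_y1`, `r_x1y2 = l_x1 (l_y2 + b l_y1)`,
#' `r_y1y2 = l_y1 l_y2 + b`, where `l` are the CC loadings and `b` the
#' Y1 -> Y2 path.
#'
#' @param spec a [common_cause_spec].
#' @return Named numeric vector `(r_x1y1, r_x1y2, r_y1y2)`.
#' @export
implied_corr_common_cause <- function(spec) {
  stopifnot(inherits(spec, "common_cause_spec"))
  implied_corr_common_cause_(spec)
}

#' Simulate data from a common-cause model
#'
#' Latent CC is standard normal; observed variables are built from the
#' stated loadings plus unique normal residuals scaled for unit population
#' variance. Columns are labeled `X@1`, `Y@1`, `Y@2`.
#'
#' @param spec a [common_cause_spec].
#' @param n number of subjects.
#' @param seed integer seed.
#' @return A [panel_data] object (population-standardized, not empirically).
#' @export
simulate_common_cause <- function(spec, n, seed = 1) {
  stopifnot(inherits(spec, "common_cause_spec"))
  n <- as.integer(n)
  if (n < 10L) stop("n must be >= 10")
  cc <- with_local_seed(substream_seed(seed, 0L), stats::rnorm(n))
  e <- with_local_seed(substream_seed(seed, 1L),
                       matrix(stats::rnorm(3L * n), n, 3L))
  x1 <- spec$load_cc_x1 * cc + sqrt(spec$unique[["x1"]]) * e[, 1L]
  y1 <- spec$load_cc_y1 * cc + sqrt(spec$unique[["y1"]]) * e[, 2L]
  y2 <- spec$load_cc_y2 * cc + spec$auto_y1_y2 * y1 +
    sqrt(spec$unique[["y2"]]) * e[, 3L]
  out <- cbind(x1, y1, y2)
  colnames(out) <- c("X@1", "Y@1", "Y@2")
  panel_data(out)
}
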