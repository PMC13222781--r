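# Fixture builders shared across test files. Everything is generated in code;
# no stored data.

# random 3x3-PSD correlation triple with safe denominators
rand_psd_triple <- function() {
  repeat {
    b <- matrix(stats::rnorm(9), 3)
    r <- stats::cov2cor(crossprod(b) + diag(stats::runif(3, 0.2, 1)))
    if (max(abs(r[upper.tri(r)])) < 0.95) {
      return(corr_triple(r[1, 2], r[1, 3], r[2, 3]))
    }
  }
}

# random valid MoSLA parameter set (not necessarily standardized)
rand_mosla_params <- function() {
  phi_n <- stats::runif(1, 0.2, 0.6)
  phi_c <- stats::runif(1, 0.2, 0.6)
  mosla_params(
    phi_n = phi_n, phi_c = phi_c,
    phi_nc = stats::runif(1, -0.8, 0.8) * sqrt(phi_n * phi_c),
    psi = stats::runif(1, 0.05, 0.5),
    rho = stats::runif(1, -0.7, 0.7),
    theta = stats::runif(1, 0.1, 0.5)
  )
}

# unit-variance 9x9 correlation matrix over three constructs x three waves,
# built from a three-trait + shared-AR(1)-state + residual process (so it is
# PSD by construction and every construct pair behaves like a MoSLA pair)
make_study_corr <- function(psi = 0.3, rho = 0.5, theta = 0.3) {
  constructs <- c("MPEE", "MNEE", "CU")
  r_tr <- matrix(c(1, -0.4, -0.3,
                   -0.4, 1, 0.35,
                   -0.3, 0.35, 1), 3, 3)
  phi <- 0.4 * r_tr  # trait covariance; total variance 0.4+psi+theta = 1
  labels <- as.vector(vapply(constructs, panel_label, character(3), wave = 1:3))
  con <- rep(1:3, each = 3)
  wave <- rep(1:3, 3)
  p <- length(labels)
  m <- matrix(0, p, p, dimnames = list(labels, labels))
  for (i in 1:p) for (j in 1:p) {
    m[i, j] <- phi[con[i], con[j]] + psi * rho^abs(wave[i] - wave[j]) +
      (i == j) * theta
  }
  # break the time-reversal symmetry of the pure shared-state process so that
  # cor(A_t, B_{t+1}) != cor(B_t, A_{t+1}) and reversed panels differ, as in
  # real cross-lagged data; perturbations keep the matrix symmetric and PSD
  bump <- function(a, b, d) {
    m[a, b] <<- m[a, b] + d
    m[b, a] <<- m[b, a] + d
  }
  bump("MPEE@1", "CU@2", -0.04); bump("MPEE@2", "CU@3", -0.03)
  bump("MNEE@1", "CU@2", 0.05);  bump("MNEE@2", "CU@3", 0.04)
  bump("MPEE@1", "MNEE@2", -0.03)
  long_corr(m)
}

# the sign-flip correlation triple used in several worked examples
triple_worked <- function() corr_triple(0.4, 0.35, 0.6)

target_from_triple <- function(r) {
  long_corr(matrix(c(1, r$r_x1y1, r$r_x1y2,
                     r$r_x1y1, 1, r$r_y1y2,
                     r$r_x1y2, r$r_y1y2, 1), 3, 3),
            labels = c("X@1", "Y@1", "Y@2"))
}
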