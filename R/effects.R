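# Difference-score effect variants: the effect of an initial exposure X1 on
# the outcome change score Y2 - Y1, (a) adjusting for the initial outcome Y1
# (identical to the traditional cross-lagged effect), (b) adjusting for the
# subsequent outcome Y2 (a time-reversed scrutiny), (c) unadjusted.

VARIANTS <- c("adjust_initial", "adjust_subsequent", "unadjusted")

#' Correlation triple for one exposure-outcome timeframe
#'
#' The three Pearson correlations that fully determine the standardized
#' difference-score effects: `r_x1y1` (exposure with initial outcome),
#' `r_x1y2` (exposure with subsequent outcome), `r_y1y2` (outcome
#' stability). The implied 3x3 correlation matrix must be positive
#' semidefinite.
#'
#' @param r_x1y1,r_x1y2,r_y1y2 correlations in `[-1, 1]`.
#' @return An object of class `corr_triple`.
#' @export
corr_triple <- function(r_x1y1, r_x1y2, r_y1y2) {
  r <- c(r_x1y1 = r_x1y1, r_x1y2 = r_x1y2, r_y1y2 = r_y1y2)
  if (!all(is.finite(r)) || any(abs(r) > 1)) {
    stop("correlations must be finite and in [-1, 1]")
  }
  m <- matrix(c(1, r[1], r[2],
                r[1], 1, r[3],
                r[2], r[3], 1), 3, 3)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("the implied 3x3 correlation matrix is not positive semidefinite")
  }
  structure(as.list(r), class = "corr_triple")
}

#' Closed-form standardized difference-score effects
#'
#' Given standardized X1, Y1, Y2, the three variant coefficients are
#' functions of the correlations alone:
#' \deqn{a_1 = \frac{r_{x1,y2} - r_{x1,y1}\, r_{y1,y2}}{1 - r_{x1,y1}^2}}
#' \deqn{b_1 = \frac{r_{x1,y2}\, r_{y1,y2} - r_{x1,y1}}{1 - r_{x1,y2}^2}}
#' \deqn{c_1 = r_{x1,y2} - r_{x1,y1}}
#'
#' `a_1` equals the traditional cross-lagged effect of X1 on Y2 adjusting
#' for Y1. `c_1` is the unadjusted OLS slope of the difference score on X1;
#' note that one published rendering of this formula is typographically
#' self-cancelling (`r_x1y2 - r_x1y2`), and the corrected form above is the
#' one consistent with ordinary least squares (see the methods vignette).
#'
#' @param r a [corr_triple] (or a length-3 numeric `(r_x1y1, r_x1y2,
#'   r_y1y2)`).
#' @return Named numeric vector `c(a1, b1, c1)`.
#' @export
closed_form_effects <- function(r) {
  if (!inherits(r, "corr_triple")) {
    r <- corr_triple(r[[1]], r[[2]], r[[3]])
  }
  if (abs(r$r_x1y1) >= 1 - 1e-12 || abs(r$r_x1y2) >= 1 - 1e-12) {
    stop("degenerate denominator: |r_x1y1| or |r_x1y2| is 1")
  }
  c(a1 = (r$r_x1y2 - r$r_x1y1 * r$r_y1y2) / (1 - r$r_x1y1^2),
    b1 = (r$r_x1y2 * r$r_y1y2 - r$r_x1y1) / (1 - r$r_x1y2^2),
    c1 = r$r_x1y2 - r$r_x1y1)
}

#' Fit one difference-score regression
#'
#' Ordinary least squares of the change score `Y2 - Y1` on the standardized
#' exposure `X1`, plus the variant's adjustment covariate (`Y1` for
#' `"adjust_initial"`, `Y2` for `"adjust_subsequent"`, none for
#' `"unadjusted"`). An intercept is always fitted (it vanishes for
#' standardized data). Standard errors are conventional homoskedastic OLS
#' standard errors with residual df `n - #coefficients`.
#'
#' @param data a standardized [panel_data] object.
#' @param exposure column label of X1 (e.g. `"MPEE@1"`).
#' @param outcome_pair character vector of length 2: the initial and
#'   subsequent outcome columns `(Y1, Y2)`.
#' @param variant one of `"adjust_initial"`, `"adjust_subsequent"`,
#'   `"unadjusted"`.
#' @return An object of class `effect_estimate`: list with elements
#'   `coefficient`, `se`, `variant`, `exposure`, `outcome`, `timeframe`,
#'   `n`, `intercept`, `adjust_coefficient`, `residual_sd`.
#' @export
fit_difference_model <- function(data, exposure, outcome_pair,
                                 variant = VARIANTS) {
  variant <- match.arg(variant, VARIANTS)
  x <- as.matrix(data)
  if (!isTRUE(attr(data, "standardized"))) {
    m <- colMeans(x)
    s <- apply(x, 2L, sd_pop)
    if (max(abs(m)) > 1e-8 || max(abs(s - 1)) > 1e-8) {
      stop("data must be standardized (use standardize_panel())")
    }
  }
  vars <- c(exposure, outcome_pair)
  if (length(outcome_pair) != 2L) stop("outcome_pair must have length 2")
  if (anyDuplicated(vars)) stop("exposure and outcome variables must be distinct")
  missing <- setdiff(vars, colnames(x))
  if (length(missing)) stop("variable(s) not in data: ",
                            paste(missing, collapse = ", "))

  y1 <- x[, outcome_pair[1L]]
  y2 <- x[, outcome_pair[2L]]
  x1 <- x[, exposure]
  d <- y2 - y1
  adj <- switch(variant,
                adjust_initial = y1,
                adjust_subsequent = y2,
                unadjusted = NULL)
  if (is.null(adj)) {
    design <- cbind(x1 = x1)
  } else {
    if (abs(stats::cor(x1, adj)) > 1 - 1e-12) {
      stop("collinear design: exposure and adjustment covariate are ",
           "perfectly correlated")
    }
    design <- cbind(x1 = x1, adj = adj)
  }
  fit <- stats::lm(d ~ design)
  sm <- summary(fit)$coefficients  # rows: intercept, x1, then adjustment
  exp_info <- parse_panel_labels(exposure)
  out_info <- parse_panel_labels(outcome_pair)
  structure(list(
    coefficient = unname(sm[2L, "Estimate"]),
    se = unname(sm[2L, "Std. Error"]),
    variant = variant,
    exposure = exp_info$construct,
    outcome = out_info$construct[1L],
    timeframe = sort(out_info$wave),
    n = nrow(x),
    intercept = unname(sm[1L, "Estimate"]),
    adjust_coefficient = if (is.null(adj)) NA_real_ else
      unname(sm[3L, "Estimate"]),
    residual_sd = summary(fit)$sigma
  ), class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s -> d(%s) [t%d->t%d], %s: coef = %.4f (SE %.4f, n = %d)\n",
              x$exposure, x$outcome, x$timeframe[1], x$timeframe[2],
              x$variant, x$coefficient, x$se, x$n))
  invisible(x)
}

#' All six difference-score effects of a panel
#'
#' For one exposure construct and one outcome construct observed at waves
#' 1-3, computes the six effects in the canonical report order: the two
#' adjust-initial effects (t1->t2, t2->t3), the two adjust-subsequent
#' effects, then the two unadjusted effects. Data are standardized
#' (population divisor) before any model if not already.
#'
#' @param data a [panel_data] with both constructs at waves 1-3.
#' @param exposure_construct,outcome_construct construct names (distinct).
#' @return A list of six [fit_difference_model()] estimates, class
#'   `panel_effects`.
#' @export
panel_effects <- function(data, exposure_construct, outcome_construct) {
  if (identical(exposure_construct, outcome_construct)) {
    stop("exposure and outcome constructs must differ")
  }
  check_complete_grid(data, c(exposure_construct, outcome_construct), 3L)
  if (!isTRUE(attr(data, "standardized"))) data <- standardize_panel(data)
  grid <- list(
    list(variant = "adjust_initial", t = 1L),
    list(variant = "adjust_initial", t = 2L),
    list(variant = "adjust_subsequent", t = 1L),
    list(variant = "adjust_subsequent", t = 2L),
    list(variant = "unadjusted", t = 1L),
    list(variant = "unadjusted", t = 2L)
  )
  est <- lapply(grid, function(g) {
    fit_difference_model(
      data,
      exposure = panel_label(exposure_construct, g$t),
      outcome_pair = panel_label(outcome_construct, c(g$t, g$t + 1L)),
      variant = g$variant
    )
  })
  structure(est, class = "panel_effects",
            exposure = exposure_construct, outcome = outcome_construct)
}

#' @export
as.data.frame.panel_effects <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x), function(i) {
    e <- x[[i]]
    data.frame(effect = i, variant = e$variant, exposure = e$exposure,
               outcome = e$outcome,
               timeframe = sprintf("t%d->t%d", e$timeframe[1], e$timeframe[2]),
               estimate = e$coefficient, se = e$se, n = e$n,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.panel_effects <- function(x, ...) {
  cat("Difference-score effects:", attr(x, "exposure"), "->",
      attr(x, "outcome"), "\n")
  print(as.data.frame(x), digits = 4, row.names = FALSE)
  invisible(x)
}
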