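# End-to-end scrutiny pipeline: four exposure-outcome panels of six
# difference-score effects each, a random-effects pooling per panel
# ("effect 7"), and a MoSLA fit for one (or every) construct pair.

default_panels <- function() {
  list(A = c(exposure = "MPEE", outcome = "CU"),
       B = c(exposure = "CU", outcome = "MPEE"),
       C = c(exposure = "MNEE", outcome = "CU"),
       D = c(exposure = "CU", outcome = "MNEE"))
}

# tiny FNV-1a hash over a string, for config provenance
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Build a scrutiny configuration
#'
#' Exactly one input source must be given: subject-level `data`, a
#' correlation matrix `corr` plus `n` (exact-mode data is then generated so
#' that all effects reproduce the matrix's closed forms), or a simulation
#' recipe `sim` (a list with `model` one of `"mosla"`, `"corr"`,
#' `"common_cause"` and the generator's arguments).
#'
#' @param data a [panel_data] object or path to a panel data file.
#' @param corr a [long_corr] object or path to a correlation matrix file.
#' @param n sample size accompanying `corr`.
#' @param sim simulation recipe list, e.g.
#'   `list(model = "mosla", params = mosla_params(), n = 561, waves = 3)`.
#' @param panels named list of `c(exposure =, outcome =)` construct pairs;
#'   defaults to the four study panels (MPEE->CU, CU->MPEE, MNEE->CU,
#'   CU->MNEE).
#' @param mosla_pair length-2 character vector naming the construct pair for
#'   the MoSLA fit (default MNEE and CU), or `NULL` to skip it.
#' @param fit_all_pairs logical; fit the MoSLA to every panel's pair.
#' @param tau2_method `"REML"` or `"DL"`.
#' @param chi2_multiplier `"nm1"` or `"n"`.
#' @param alpha two-sided significance level for effect flags.
#' @param seed integer seed for any simulation.
#' @return An object of class `scrutiny_config`.
#' @export
scrutiny_config <- function(data = NULL, corr = NULL, n = NULL, sim = NULL,
                            panels = default_panels(),
                            mosla_pair = c("MNEE", "CU"),
                            fit_all_pairs = FALSE,
                            tau2_method = c("REML", "DL"),
                            chi2_multiplier = c("nm1", "n"),
                            alpha = 0.05, seed = 1L) {
  sources <- c(!is.null(data), !is.null(corr), !is.null(sim))
  if (sum(sources) == 0L) stop("one of data, corr or sim must be supplied")
  if (sum(sources) > 1L) {
    stop("config conflict: supply exactly one of data, corr or sim")
  }
  if (!is.null(corr) && is.null(n)) stop("a correlation matrix requires n")
  for (p in panels) {
    if (p[["exposure"]] == p[["outcome"]]) {
      stop("panel with exposure equal to outcome: ", p[["exposure"]])
    }
  }
  if (is.character(data)) data <- read_panel_data(data)
  if (is.character(corr)) corr <- read_corr_matrix(corr)
  structure(list(
    data = data, corr = corr, n = n, sim = sim, panels = panels,
    mosla_pair = mosla_pair, fit_all_pairs = isTRUE(fit_all_pairs),
    tau2_method = match.arg(tau2_method),
    chi2_multiplier = match.arg(chi2_multiplier),
    alpha = alpha, seed = as.integer(seed)
  ), class = "scrutiny_config")
}

resolve_dataset <- function(config) {
  if (!is.null(config$data)) return(panel_data(config$data))
  if (!is.null(config$corr)) {
    return(simulate_from_corr(config$corr, n = config$n, seed = config$seed,
                              exact = TRUE))
  }
  sim <- config$sim
  switch(sim$model,
         mosla = simulate_mosla(
           params = if (is.null(sim$params)) mosla_params() else sim$params,
           n = if (is.null(sim$n)) 561L else sim$n,
           waves = if (is.null(sim$waves)) 3L else sim$waves,
           seed = config$seed,
           constructs = if (is.null(sim$constructs)) c("MNEE", "CU")
                        else sim$constructs),
         corr = simulate_from_corr(sim$target, n = sim$n, seed = config$seed,
                                   exact = !isTRUE(sim$exact == FALSE)),
         common_cause = simulate_common_cause(sim$spec, n = sim$n,
                                              seed = config$seed),
         stop("unknown simulation model: ", sim$model))
}

#' Run the full scrutiny pipeline
#'
#' Resolves the input dataset (given, exact-simulated from a correlation
#' matrix, or simulated from a generating model), standardizes it, computes
#' each configured panel's six difference-score effects and their
#' random-effects pooling, flags two-sided significance at the configured
#' alpha, and fits the MoSLA to the configured construct pair(s). The whole
#' run is deterministic for a fixed config and seed.
#'
#' @param config a [scrutiny_config()].
#' @param quiet suppress per-stage progress messages.
#' @return An object of class `scrutiny_report`.
#' @export
run_scrutiny <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "scrutiny_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  say("[resolve] seed=%d", config$seed)
  data <- resolve_dataset(config)
  if (!isTRUE(attr(data, "standardized"))) data <- standardize_panel(data)
  crit <- stats::qnorm(1 - config$alpha / 2)

  available <- unique(parse_panel_labels(colnames(data))$construct)
  panels <- Filter(function(p) all(p %in% available), config$panels)
  if (!length(panels)) stop("no configured panel's constructs are in the data")

  panel_results <- lapply(names(panels), function(id) {
    p <- panels[[id]]
    say("[panel %s] %s -> %s", id, p[["exposure"]], p[["outcome"]])
    eff <- panel_effects(data, p[["exposure"]], p[["outcome"]])
    pooled <- pool_random_effects(eff, method = config$tau2_method)
    list(id = id, exposure = p[["exposure"]], outcome = p[["outcome"]],
         effects = eff, pooled = pooled)
  })
  names(panel_results) <- names(panels)

  mosla_fits <- list()
  pairs <- if (config$fit_all_pairs) {
    unique(lapply(panel_results, function(pr) sort(c(pr$exposure, pr$outcome))))
  } else if (!is.null(config$mosla_pair) &&
             all(config$mosla_pair %in% available)) {
    list(config$mosla_pair)
  } else {
    list()
  }
  S_all <- cov_pop(data)   # correlation matrix: data standardized, n divisor
  for (pair in pairs) {
    key <- paste(pair, collapse = "-")
    say("[mosla] %s", key)
    vars <- as.vector(vapply(pair, panel_label, character(3L), wave = 1:3))
    fit <- fit_mosla(S_all[vars, vars], n = nrow(data),
                     spec = build_mosla_spec(3L, pair),
                     chi2_multiplier = config$chi2_multiplier,
                     seed = config$seed)
    mosla_fits[[key]] <- list(fit = fit, indices = fit_indices(fit),
                              standardized = standardized_solution(fit))
  }

  cfg_for_hash <- config
  cfg_for_hash$data <- NULL  # hash the declarative part only
  provenance <- list(
    seed = config$seed,
    config_hash = fnv1a_hash(paste(utils::capture.output(
      utils::str(cfg_for_hash)), collapse = "\n")),
    package_version = as.character(utils::packageVersion("clpmscrutiny")),
    n = nrow(data)
  )
  say("[done] %.2fs", proc.time()[["elapsed"]] - t0)
  structure(list(panels = panel_results, mosla = mosla_fits,
                 alpha = config$alpha, z_crit = crit,
                 provenance = provenance),
            class = "scrutiny_report")
}

#' Tabulate a scrutiny report
#'
#' One row per panel and effect: effects 1-6 are the difference-score
#' variants in canonical order, effect 7 is the random-effects pooling.
#'
#' @param x a `scrutiny_report`.
#' @param ... unused.
#' @return A data frame with columns `panel`, `effect`, `variant`,
#'   `timeframe`, `estimate`, `se`, `ci_low`, `ci_high`, `p`, `significant`.
#' @export
as.data.frame.scrutiny_report <- function(x, ...) {
  z <- x$z_crit
  rows <- lapply(x$panels, function(pr) {
    eff <- lapply(seq_along(pr$effects), function(i) {
      e <- pr$effects[[i]]
      zval <- e$coefficient / e$se
      data.frame(panel = pr$id, effect = i, variant = e$variant,
                 timeframe = sprintf("t%d->t%d", e$timeframe[1],
                                     e$timeframe[2]),
                 estimate = e$coefficient, se = e$se,
                 ci_low = e$coefficient - z * e$se,
                 ci_high = e$coefficient + z * e$se,
                 p = 2 * stats::pnorm(-abs(zval)),
                 significant = abs(zval) > z,
                 stringsAsFactors = FALSE)
    })
    pl <- pr$pooled
    zval <- pl$estimate / pl$se
    eff[[7L]] <- data.frame(panel = pr$id, effect = 7L, variant = "pooled",
                            timeframe = "t1->t3",
                            estimate = pl$estimate, se = pl$se,
                            ci_low = pl$ci_low, ci_high = pl$ci_high,
                            p = 2 * stats::pnorm(-abs(zval)),
                            significant = abs(zval) > z,
                            stringsAsFactors = FALSE)
    do.call(rbind, eff)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.scrutiny_report <- function(x, ...) {
  cat("Scrutiny report:", length(x$panels), "panel(s),",
      length(x$mosla), "MoSLA fit(s), seed", x$provenance$seed, "\n\n")
  print(as.data.frame(x), digits = 4, row.names = FALSE)
  for (key in names(x$mosla)) {
    cat("\nMoSLA [", key, "]: ", sep = "")
    print(x$mosla[[key]]$indices)
  }
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

report_to_list <- function(report) {
  list(
    panels = lapply(report$panels, function(pr) {
      list(id = pr$id, exposure = pr$exposure, outcome = pr$outcome,
           effects = lapply(pr$effects, function(e) {
             e$timeframe <- as.integer(e$timeframe)
             unclass(e)
           }),
           pooled = unclass(pr$pooled))
    }),
    mosla = lapply(report$mosla, function(m) {
      list(theta_hat = unclass(m$fit$theta_hat),
           se = as.list(m$fit$se),
           n = m$fit$n, F_min = m$fit$F_min,
           chi2 = m$fit$chi2, df = m$fit$df, p_value = m$fit$p_value,
           chi2_multiplier = m$fit$chi2_multiplier,
           converged = m$fit$converged,
           indices = unclass(m$indices),
           standardized = m$standardized,
           S = as.data.frame(cbind(label = rownames(m$fit$S),
                                   as.data.frame(m$fit$S))))
    }),
    alpha = report$alpha, z_crit = report$z_crit,
    provenance = report$provenance
  )
}

list_to_report <- function(x) {
  panels <- lapply(x$panels, function(pr) {
    pr$effects <- lapply(pr$effects, function(e) {
      e$adjust_coefficient <- if (is.null(e$adjust_coefficient)) NA_real_
                              else e$adjust_coefficient
      structure(e, class = "effect_estimate")
    })
    class(pr$effects) <- "panel_effects"
    attr(pr$effects, "exposure") <- pr$exposure
    attr(pr$effects, "outcome") <- pr$outcome
    pr$pooled <- structure(pr$pooled, class = "pooled_effect")
    pr
  })
  mosla <- lapply(x$mosla, function(m) {
    th <- m$theta_hat
    fit <- list(theta_hat = mosla_params(th$phi_n, th$phi_c, th$phi_nc,
                                         th$psi, th$rho, th$theta),
                se = unlist(m$se), n = m$n, F_min = m$F_min, chi2 = m$chi2,
                df = m$df, p_value = m$p_value,
                chi2_multiplier = m$chi2_multiplier, converged = m$converged)
    Sdf <- m$S
    Sm <- as.matrix(Sdf[, -1L, drop = FALSE])
    rownames(Sm) <- Sdf$label
    fit$S <- Sm
    class(fit) <- "mosla_fit"
    list(fit = fit, indices = structure(m$indices, class = "fit_indices"),
         standardized = m$standardized)
  })
  structure(list(panels = panels, mosla = mosla, alpha = x$alpha,
                 z_crit = x$z_crit, provenance = x$provenance),
            class = "scrutiny_report")
}

#' Write and read scrutiny reports
#'
#' `write_report()` emits a complete machine-readable JSON file and a
#' delimited-text effect table (one row per panel and effect, 7 effects per
#' panel); optionally a forest-style plot per panel. `read_report()`
#' restores the JSON file to a `scrutiny_report`.
#'
#' @param report a `scrutiny_report`.
#' @param dir output directory (created if needed).
#' @param plots also write one forest plot PNG per panel.
#' @return `write_report()` invisibly returns the paths written;
#'   `read_report()` returns a `scrutiny_report`.
#' @export
write_report <- function(report, dir, plots = FALSE) {
  stopifnot(inherits(report, "scrutiny_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report_to_list(report), json_path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  tsv_path <- file.path(dir, "effects.tsv")
  utils::write.table(as.data.frame(report), tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(json_path, tsv_path)
  if (plots) {
    for (id in names(report$panels)) {
      png_path <- file.path(dir, paste0("forest_", id, ".png"))
      grDevices::png(png_path, width = 900, height = 500, res = 110)
      plot_forest(report, id)
      grDevices::dev.off()
      paths <- c(paths, png_path)
    }
  }
  invisible(paths)
}

#' @rdname write_report
#' @param path path to a `report.json` written by `write_report()`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = TRUE, simplifyMatrix = FALSE)
  # keep effects as lists, not collapsed data frames
  x2 <- jsonlite::read_json(path, simplifyVector = FALSE)
  x$panels <- lapply(x2$panels, function(pr) {
    pr$effects <- lapply(pr$effects, function(e) {
      e$timeframe <- as.integer(unlist(e$timeframe))
      e[c("coefficient", "se", "intercept", "residual_sd", "n")] <-
        lapply(e[c("coefficient", "se", "intercept", "residual_sd", "n")],
               as.numeric)
      e$adjust_coefficient <- if (is.null(e$adjust_coefficient))
        NA_real_ else as.numeric(e$adjust_coefficient)
      e
    })
    pr$pooled <- lapply(pr$pooled, function(v)
      if (is.character(v)) v else as.numeric(v))
    pr
  })
  x$mosla <- lapply(seq_along(x2$mosla), function(i) {
    m <- x2$mosla[[i]]
    m$theta_hat <- lapply(m$theta_hat, as.numeric)
    m$se <- lapply(m$se, as.numeric)
    m[c("n", "F_min", "chi2", "df", "p_value")] <-
      lapply(m[c("n", "F_min", "chi2", "df", "p_value")], as.numeric)
    m$indices <- lapply(m$indices, function(v)
      if (is.character(v)) v else as.numeric(v))
    simp <- x$mosla[[i]]
    m$standardized <- simp$standardized
    m$S <- simp$S
    m
  })
  names(x$mosla) <- names(x2$mosla)
  list_to_report(x)
}

#' Forest-style plot of a panel's seven effects
#'
#' Plots effects 1-6 and the pooled effect 7 with their confidence
#' intervals, ordered top to bottom as in the report table.
#'
#' @param report a `scrutiny_report`.
#' @param panel panel id (e.g. `"A"`).
#' @export
plot_forest <- function(report, panel) {
  tab <- as.data.frame(report)
  tab <- tab[tab$panel == panel, ]
  if (!nrow(tab)) stop("no panel '", panel, "' in report")
  pr <- report$panels[[panel]]
  k <- nrow(tab)
  y <- rev(seq_len(k))
  xlim <- range(c(tab$ci_low, tab$ci_high, 0))
  graphics::plot(tab$estimate, y, pch = c(rep(15, k - 1), 18),
                 cex = c(rep(1, k - 1), 1.6),
                 xlim = xlim + c(-0.05, 0.05) * diff(xlim),
                 ylim = c(0.5, k + 0.5), yaxt = "n",
                 xlab = "standardized effect", ylab = "",
                 main = sprintf("Panel %s: %s -> %s", panel, pr$exposure,
                                pr$outcome))
  graphics::segments(tab$ci_low, y, tab$ci_high, y)
  graphics::abline(v = 0, lty = 3, col = "grey40")
  graphics::axis(2, at = y, las = 1, cex.axis = 0.8,
                 labels = sprintf("%d: %s %s", tab$effect, tab$variant,
                                  tab$timeframe))
  invisible(tab)
}
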