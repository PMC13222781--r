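# ---- internal helpers -------------------------------------------------------

# Population-divisor (n) standard deviation. The package standardizes with the
# n divisor everywhere so that exact-mode simulation reproduces a target
# correlation matrix without n/(n-1) drift.
sd_pop <- function(x) {
  n <- length(x)
  sqrt(sum((x - mean(x))^2) / n)
}

cov_pop <- function(x) {
  x <- as.matrix(x)
  xc <- sweep(x, 2L, colMeans(x))
  crossprod(xc) / nrow(x)
}

# Evaluate a function with a temporary RNG state; the caller's global
# .Random.seed is restored on exit.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-stream seed: mixing a base seed with a stream id so that
# adding waves/streams never perturbs draws of earlier streams.
substream_seed <- function(seed, stream) {
  ((as.double(seed %% 65011L) * 33013 + as.double(stream) * 7907 + 17) %%
     2147483629)
}

# ---- variable labels --------------------------------------------------------

#' Compose and parse CONSTRUCT@WAVE variable labels
#'
#' Panel variables are labeled `CONSTRUCT@WAVE`, e.g. `"MNEE@1"`, `"CU@3"`.
#'
#' @param construct character vector of construct names (no `"@"`).
#' @param wave integer vector of 1-based wave indices.
#' @return `panel_label()` returns a character vector;
#'   `parse_panel_labels()` a data frame with columns `construct` and `wave`.
#' @examples
#' panel_label("CU", 1:3)
#' parse_panel_labels(c("MNEE@1", "CU@2"))
#' @export
panel_label <- function(construct, wave) {
  stopifnot(!grepl("@", construct, fixed = TRUE))
  paste0(construct, "@", as.integer(wave))
}

#' @rdname panel_label
#' @param labels character vector of `CONSTRUCT@WAVE` labels.
#' @export
parse_panel_labels <- function(labels) {
  ok <- grepl("^[^@]+@[0-9]+$", labels)
  if (!all(ok)) {
    stop("malformed variable label(s): ",
         paste(labels[!ok], collapse = ", "),
         " (expected CONSTRUCT@WAVE, e.g. \"CU@1\")")
  }
  parts <- strsplit(labels, "@", fixed = TRUE)
  data.frame(
    label = labels,
    construct = vapply(parts, `[`, "", 1L),
    wave = as.integer(vapply(parts, `[`, "", 2L)),
    stringsAsFactors = FALSE
  )
}

# ---- panel_data -------------------------------------------------------------

#' Subject-level panel dataset
#'
#' A `panel_data` object is a numeric matrix with one row per subject and one
#' `CONSTRUCT@WAVE` column per construct-wave variable, plus a `standardized`
#' flag. Scores must be complete (no missing values); each construct's wave
#' indices must be consecutive starting at 1.
#'
#' @param scores numeric matrix or data frame, columns named `CONSTRUCT@WAVE`.
#' @param standardized logical; when `TRUE`, every column must have mean 0 and
#'   population-divisor SD 1 to within `1e-8`.
#' @return An object of class `panel_data` (a numeric matrix with attributes).
#' @seealso [standardize_panel()], [read_panel_data()]
#' @export
panel_data <- function(scores, standardized = FALSE) {
  x <- as.matrix(scores)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) stop("panel data must have CONSTRUCT@WAVE column names")
  if (anyNA(x) || any(!is.finite(x))) stop("panel data must be complete and finite")
  info <- parse_panel_labels(colnames(x))
  if (anyDuplicated(colnames(x))) stop("duplicate variable labels")
  for (con in unique(info$construct)) {
    w <- sort(info$wave[info$construct == con])
    if (!identical(w, seq_along(w))) {
      stop("waves of construct '", con, "' must be consecutive starting at 1")
    }
  }
  if (standardized) {
    m <- colMeans(x)
    s <- apply(x, 2L, sd_pop)
    if (max(abs(m)) > 1e-8 || max(abs(s - 1)) > 1e-8) {
      stop("data flagged standardized but columns are not (mean 0, SD 1, ",
           "population divisor)")
    }
  }
  structure(x, class = c("panel_data", "matrix", "array"),
            standardized = isTRUE(standardized))
}

#' Standardize panel columns (population divisor)
#'
#' Centers each column and scales by its population-divisor (n) standard
#' deviation, so that the empirical correlation matrix with the same divisor
#' is exactly the cross-product of the result divided by n.
#'
#' @param data a [panel_data] object or coercible matrix.
#' @return A standardized `panel_data` object.
#' @export
standardize_panel <- function(data) {
  x <- as.matrix(data)
  s <- apply(x, 2L, sd_pop)
  if (any(s <= 0)) stop("cannot standardize a constant column")
  z <- sweep(sweep(x, 2L, colMeans(x)), 2L, s, "/")
  panel_data(z, standardized = TRUE)
}

#' @export
print.panel_data <- function(x, ...) {
  info <- parse_panel_labels(colnames(x))
  cat("Panel dataset: ", nrow(x), " subjects, ",
      length(unique(info$construct)), " construct(s) x ",
      max(info$wave), " wave(s)",
      if (isTRUE(attr(x, "standardized"))) " (standardized)", "\n", sep = "")
  cat("Variables:", paste(colnames(x), collapse = ", "), "\n")
  invisible(x)
}

# require that data contains constructs at waves 1..3 (or 1..waves)
check_complete_grid <- function(data, constructs, waves) {
  need <- as.vector(vapply(constructs, panel_label, character(waves),
                           wave = seq_len(waves)))
  missing <- setdiff(need, colnames(data))
  if (length(missing)) {
    stop("panel data is missing required variable(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

# ---- long_corr --------------------------------------------------------------

#' Labeled longitudinal correlation matrix
#'
#' A symmetric positive semidefinite correlation matrix over
#' `CONSTRUCT@WAVE` variables, with unit diagonal. Symmetry is checked to
#' `1e-12`, the smallest eigenvalue must exceed `-1e-10`.
#'
#' @param values square numeric matrix with `CONSTRUCT@WAVE` dimnames (or
#'   unnamed, in which case `labels` must be supplied).
#' @param labels optional character vector of labels for rows/columns.
#' @return An object of class `long_corr`.
#' @export
long_corr <- function(values, labels = NULL) {
  x <- as.matrix(values)
  if (!is.null(labels)) dimnames(x) <- list(labels, labels)
  if (is.null(colnames(x))) stop("correlation matrix must be labeled")
  if (nrow(x) != ncol(x)) stop("correlation matrix must be square")
  if (!identical(rownames(x), colnames(x))) stop("row/column labels differ")
  if (anyDuplicated(colnames(x))) stop("duplicate labels")
  parse_panel_labels(colnames(x))
  if (max(abs(x - t(x))) > 1e-12) stop("matrix is not symmetric (tol 1e-12)")
  x <- (x + t(x)) / 2
  if (max(abs(diag(x) - 1)) > 1e-8) stop("diagonal must be 1")
  ev <- eigen(x, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("matrix is not positive semidefinite (min eigenvalue ",
         format(min(ev)), ")")
  }
  if (max(abs(x)) > 1 + 1e-12) stop("correlations must lie in [-1, 1]")
  structure(x, class = c("long_corr", "matrix", "array"))
}

#' @export
print.long_corr <- function(x, digits = 3, ...) {
  cat("Longitudinal correlation matrix (", ncol(x), " variables)\n", sep = "")
  print(round(unclass(x), digits))
  invisible(x)
}

# ---- file I/O ---------------------------------------------------------------

#' Read and write labeled correlation matrices and panel data files
#'
#' Delimited text formats: a correlation matrix file has `CONSTRUCT@WAVE`
#' labels in the first row and first column; a panel data file has a header of
#' `CONSTRUCT@WAVE` columns and one row per subject.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return `read_corr_matrix()` a [long_corr]; `read_panel_data()` a
#'   [panel_data].
#' @export
read_corr_matrix <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  long_corr(as.matrix(df))
}

#' @rdname read_corr_matrix
#' @param x object to write.
#' @export
write_corr_matrix <- function(x, path, sep = "\t") {
  m <- as.matrix(x)
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_corr_matrix
#' @param standardized passed to [panel_data()].
#' @export
read_panel_data <- function(path, sep = "\t", standardized = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  panel_data(as.matrix(df), standardized = standardized)
}

#' @rdname read_corr_matrix
#' @export
write_panel_data <- function(x, path, sep = "\t") {
  utils::write.table(as.matrix(x), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
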