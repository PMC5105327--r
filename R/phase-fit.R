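# Periodic spline fitting of gene expression over circadian time, and the
# derived phase statistics: peak time (argmax of the fitted curve), trough
# time (argmin) and the rhythmicity signal-to-noise ratio
# SNR = (max f - min f) / s, with s the root-mean-square residual.

#' Fit a periodic spline to expression over circadian time
#'
#' Least-squares fit of a cyclic cubic B-spline basis with period 24 h and
#' `n_knots` evenly spaced knots (at 0, 8 and 16 h by default). The cyclic
#' basis matches value, first and second derivative across the 0/24 h seam,
#' so the fitted curve `f(t)` is smooth on the circle with
#' `f(0) == f(24)`. The basis spans constants, so no separate intercept is
#' needed; the fit has `n_knots` free coefficients and is deterministic
#' given the data.
#'
#' The root-mean-square error uses the plain `n` denominator:
#' `rmse = sqrt(mean(residuals^2))`.
#'
#' @param times observation times, hours (reduced modulo 24). The times
#'   must cover at least half the circle: the longest empty arc between
#'   consecutive (sorted, circular) observation times must be <= 12 h.
#' @param values finite expression values, one per time.
#' @param n_knots number of knots (default 3, which constrains the fit to
#'   near-sinusoidal flexibility).
#' @return object of class `periodic_spline_fit` with elements `n_knots`,
#'   `knots`, `coefficients`, `rmse`, `n_samples`.
#' @seealso [peak_time()], [trough_time()], [snr()]
#' @examples
#' t <- seq(0, 23, by = 1)
#' fit <- fit_periodic_spline(t, cos(2 * pi * (t - 8) / 24))
#' peak_time(fit)
#' @export
fit_periodic_spline <- function(times, values, n_knots = 3L) {
  if (!is.numeric(times) || !is.numeric(values))
    stop("times and values must be numeric")
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (!all(is.finite(times)) || !all(is.finite(values)))
    stop("times and values must be finite")
  n_knots <- as.integer(n_knots)
  if (n_knots < 3L) stop("need at least 3 knots for a cyclic cubic basis")
  n <- length(values)
  if (n < 2L * n_knots)
    stop(sprintf("need at least %d observations for %d knots, got %d",
                 2L * n_knots, n_knots, n))
  t24 <- wrap24(times)
  ts <- sort(unique(t24))
  longest_gap <- max(diff(c(ts, ts[1L] + 24)))
  if (24 - longest_gap < 12)
    stop("observation times cover less than 12 h of the circadian cycle")
  knots <- seq(0, 24, length.out = n_knots + 1L)
  X <- mgcv::cSplineDes(t24, knots)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient spline design (times too clustered)")
  ls <- stats::lm.fit(X, values)
  structure(
    list(n_knots = n_knots,
         knots = knots,
         coefficients = unname(ls$coefficients),
         rmse = sqrt(mean(ls$residuals^2)),
         n_samples = n),
    class = "periodic_spline_fit")
}

#' Evaluate a fitted periodic spline
#'
#' @param object a `periodic_spline_fit`.
#' @param times hours at which to evaluate (any real; reduced modulo 24).
#' @param ... unused.
#' @return fitted values `f(times)`.
#' @export
predict.periodic_spline_fit <- function(object, times, ...) {
  t <- wrap24(times)
  # pad with a non-knot point: cSplineDes miscomputes when every input
  # falls exactly on a knot (scalar-at-knot edge case)
  X <- mgcv::cSplineDes(c(t, 0.5), object$knots)
  drop(X[seq_along(t), , drop = FALSE] %*% object$coefficients)
}

#' @export
print.periodic_spline_fit <- function(x, ...) {
  cat(sprintf("Periodic spline fit: %d knots, %d samples, rmse %.4g\n",
              x$n_knots, x$n_samples, x$rmse))
  invisible(x)
}

# Golden-section search on [lo, hi]. Uses value comparisons only, so the
# returned abscissa is exactly invariant under y -> a*y + b (a > 0), and
# maxima/minima swap exactly under a < 0.
#' @noRd
.golden_section <- function(f, lo, hi, maximum = TRUE, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  fc <- f(c1); fd <- f(d1)
  while (b - a > tol) {
    keep_left <- if (maximum) fc >= fd else fc <= fd
    if (keep_left) {
      b <- d1; d1 <- c1; fd <- fc
      c1 <- b - gr * (b - a); fc <- f(c1)
    } else {
      a <- c1; c1 <- d1; fc <- fd
      d1 <- a + gr * (b - a); fd <- f(d1)
    }
  }
  (a + b) / 2
}

#' @noRd
.extremum_time <- function(fit, grid_resolution, maximum) {
  grid <- seq(0, 24, by = grid_resolution)
  grid <- grid[grid < 24]
  vals <- predict(fit, grid)
  if (diff(range(vals)) < 1e-10) {
    warning("flat fit: no ", if (maximum) "peak" else "trough",
            "; returning earliest time")
    return(structure(0, flat = TRUE))
  }
  i0 <- if (maximum) which.max(vals) else which.min(vals)
  f <- function(t) predict(fit, t)
  est <- .golden_section(f, grid[i0] - grid_resolution,
                         grid[i0] + grid_resolution,
                         maximum = maximum, tol = 1e-4)
  # guard: never return a refinement worse than the grid point
  better <- if (maximum) f(est) >= vals[i0] else f(est) <= vals[i0]
  if (!better) est <- grid[i0]
  wrap24(est)
}

#' Time of peak expression
#'
#' The argmax of the fitted curve over `[0, 24)`: a uniform grid scan at
#' `grid_resolution` locates the bracketing cell, then a golden-section
#' search refines the estimate to about 1e-4 h. Ties between grid points
#' are broken toward the smallest time. A flat (constant) fit returns 0
#' with attribute `flat = TRUE` and a warning.
#'
#' @param fit a `periodic_spline_fit`.
#' @param grid_resolution scan step, hours (default 0.1).
#' @return peak time, hours in `[0, 24)`.
#' @export
peak_time <- function(fit, grid_resolution = 0.1) {
  .extremum_time(fit, grid_resolution, maximum = TRUE)
}

#' Time of trough expression
#'
#' The argmin of the fitted curve; see [peak_time()] for the algorithm.
#'
#' @inheritParams peak_time
#' @return trough time, hours in `[0, 24)`.
#' @export
trough_time <- function(fit, grid_resolution = 0.1) {
  .extremum_time(fit, grid_resolution, maximum = FALSE)
}

#' Signal-to-noise ratio of circadian rhythmicity
#'
#' `SNR = (max f - min f) / rmse`: the peak-to-trough range of the fitted
#' curve divided by the root-mean-square residual of the fit. Genes with
#' `SNR > 1` are conventionally called rhythmic. For an (essentially)
#' interpolating fit with `rmse < 1e-12` the ratio is `Inf`, flagged with
#' attribute `noiseless = TRUE`.
#'
#' @inheritParams peak_time
#' @return non-negative scalar (possibly `Inf`).
#' @export
snr <- function(fit, grid_resolution = 0.1) {
  pk <- suppressWarnings(peak_time(fit, grid_resolution))
  tr <- suppressWarnings(trough_time(fit, grid_resolution))
  if (fit$rmse < 1e-12)
    return(structure(Inf, noiseless = TRUE))
  rng <- predict(fit, as.numeric(pk)) - predict(fit, as.numeric(tr))
  rng / fit$rmse
}

#' Estimate peak and trough phases for a panel of genes
#'
#' Fits a periodic spline per gene (within one dataset) and reports peak
#' time, trough time, SNR and sample count for every gene whose SNR
#' exceeds `snr_threshold`. Genes below the threshold are listed as
#' excluded together with their SNR; genes absent from the matrix are
#' listed as not measured.
#'
#' @param x expression matrix of one dataset (adjusted, unscaled values;
#'   phases and SNR are invariant to per-gene affine maps so scaling does
#'   not matter).
#' @param samples sample table covering the columns of `x`, with a complete
#'   `circadian_time` column.
#' @param genes gene IDs to fit (default: all rows).
#' @param snr_threshold rhythmicity threshold (default 1; strict
#'   inequality).
#' @param n_knots,grid_resolution passed to the fitting and argmax steps.
#' @return list of class `phase_estimates`:
#'   \describe{
#'     \item{estimates}{data.frame `gene_id`, `dataset_id`, `organ`,
#'       `peak_time`, `trough_time`, `snr`, `n_samples`.}
#'     \item{excluded}{data.frame `gene_id`, `snr` for sub-threshold genes.}
#'     \item{not_measured}{character vector of genes absent from `x`.}
#'   }
#' @export
estimate_phases <- function(x, samples, genes = rownames(x),
                            snr_threshold = 1, n_knots = 3L,
                            grid_resolution = 0.1) {
  validate_expression_matrix(x)
  samples <- align_samples(x, samples)
  ct <- samples$circadian_time
  if (is.null(ct) || anyNA(ct))
    stop("circadian_time must be present for all samples")
  dataset_id <- if (!is.null(samples$dataset_id) &&
                    length(unique(samples$dataset_id)) == 1L)
    unique(samples$dataset_id) else NA_character_
  organ <- if (!is.null(samples$organ) &&
               length(unique(samples$organ)) == 1L)
    unique(samples$organ) else NA_character_
  not_measured <- setdiff(genes, rownames(x))
  genes <- intersect(genes, rownames(x))
  rows <- list(); excl <- list()
  for (g in genes) {
    fit <- fit_periodic_spline(ct, x[g, ], n_knots = n_knots)
    s <- snr(fit, grid_resolution)
    if (is.infinite(s) || s > snr_threshold) {
      rows[[g]] <- data.frame(
        gene_id = g, dataset_id = dataset_id, organ = organ,
        peak_time = as.numeric(peak_time(fit, grid_resolution)),
        trough_time = as.numeric(trough_time(fit, grid_resolution)),
        snr = as.numeric(s), n_samples = fit$n_samples,
        stringsAsFactors = FALSE)
    } else {
      excl[[g]] <- data.frame(gene_id = g, snr = as.numeric(s),
                              stringsAsFactors = FALSE)
    }
  }
  empty_est <- data.frame(gene_id = character(), dataset_id = character(),
                          organ = character(), peak_time = numeric(),
                          trough_time = numeric(), snr = numeric(),
                          n_samples = integer(), stringsAsFactors = FALSE)
  empty_excl <- data.frame(gene_id = character(), snr = numeric(),
                           stringsAsFactors = FALSE)
  structure(
    list(estimates = if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE))) else empty_est,
         excluded = if (length(excl)) do.call(rbind, c(excl, list(make.row.names = FALSE))) else empty_excl,
         not_measured = not_measured),
    class = "phase_estimates")
}

#' @export
print.phase_estimates <- function(x, ...) {
  cat(sprintf("Phase estimates: %d rhythmic, %d excluded, %d not measured\n",
              nrow(x$estimates), nrow(x$excluded), length(x$not_measured)))
  if (nrow(x$estimates)) print(x$estimates, row.names = FALSE)
  invisible(x)
}
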