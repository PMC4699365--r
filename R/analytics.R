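# Post-query analytics: histograms and multi-histograms, Gaussian kernel
# density estimates, least-squares regression fits and plot comparison.

drop_missing <- function(values) values[!is.na(values) & is.finite(values)]

sturges <- function(n) max(1L, as.integer(ceiling(log2(n)) + 1))

# Shared binning: k equal-width bins over [lo, hi]; every bin right-open
# except the last, which is right-closed so the maximum lands in-range.
bin_index <- function(values, lo, hi, k) {
  w <- (hi - lo) / k
  idx <- pmin(pmax(floor((values - lo) / w), 0), k - 1) + 1L
  as.integer(idx)
}

new_histogram <- function(bin_edges, counts) {
  structure(list(bin_edges = bin_edges, counts = counts,
                 series_names = names(counts)),
            class = "histogram_result")
}

#' @export
print.histogram_result <- function(x, ...) {
  cat(sprintf("<histogram_result> %d bins, series: %s\n",
              length(x$bin_edges) - 1,
              paste(x$series_names, collapse = ", ")))
  invisible(x)
}

#' Histogram of a feature
#'
#' Equal-width bins over the data range; bins are right-open except the last
#' (right-closed), so all `n` finite values are counted. With all values
#' equal, a single unit-width bin centred on the value is used. The default
#' bin count follows Sturges' rule, `ceiling(log2(n)) + 1`.
#'
#' @param values Numeric vector; missing values are ignored.
#' @param bins Number of bins; `NULL` for Sturges' rule.
#' @param name Series name in the result.
#' @return A `histogram_result` with `bin_edges` (length `bins + 1`) and a
#'   per-series list of integer `counts`.
#' @export
histogram <- function(values, bins = NULL, name = "values") {
  values <- drop_missing(values)
  if (length(values) == 0) {
    sm_abort("sm_analytics_error", "histogram requires at least one finite value")
  }
  lo <- min(values); hi <- max(values)
  if (lo == hi) {
    edges <- c(lo - 0.5, hi + 0.5)
    counts <- stats::setNames(list(length(values)), name)
    return(new_histogram(edges, lapply(counts, as.integer)))
  }
  k <- if (is.null(bins)) sturges(length(values)) else as.integer(bins)
  if (k < 1) sm_abort("sm_analytics_error", "bins must be >= 1")
  edges <- seq(lo, hi, length.out = k + 1)
  edges[k + 1] <- hi
  counts <- tabulate(bin_index(values, lo, hi, k), nbins = k)
  new_histogram(edges, stats::setNames(list(as.integer(counts)), name))
}

#' Multi-histogram over shared bins
#'
#' Several named series binned on one shared set of edges computed over the
#' pooled range, so the distributions are directly comparable (e.g. a
#' feature in hit versus non-hit populations).
#'
#' @param series Named list of numeric vectors.
#' @param bins Number of bins; `NULL` applies Sturges' rule to the pooled
#'   sample.
#' @return A `histogram_result` with one count vector per series.
#' @export
multihistogram <- function(series, bins = NULL) {
  if (length(series) == 0) {
    sm_abort("sm_analytics_error", "multihistogram requires at least one series")
  }
  if (is.null(names(series)) || !all(nzchar(names(series)))) {
    names(series) <- paste0("series", seq_along(series))
  }
  cleaned <- lapply(series, drop_missing)
  for (nm in names(cleaned)) {
    if (length(cleaned[[nm]]) == 0) {
      sm_abort("sm_analytics_error",
               sprintf("series '%s' has no finite values", nm))
    }
  }
  pooled <- unlist(cleaned, use.names = FALSE)
  lo <- min(pooled); hi <- max(pooled)
  if (lo == hi) {
    edges <- c(lo - 0.5, hi + 0.5)
    counts <- lapply(cleaned, function(v) as.integer(length(v)))
    return(new_histogram(edges, counts))
  }
  k <- if (is.null(bins)) sturges(length(pooled)) else as.integer(bins)
  edges <- seq(lo, hi, length.out = k + 1)
  edges[k + 1] <- hi
  counts <- lapply(cleaned, function(v) {
    as.integer(tabulate(bin_index(v, lo, hi, k), nbins = k))
  })
  new_histogram(edges, counts)
}

#' Gaussian kernel density estimate
#'
#' Exact (non-binned) KDE with a Gaussian kernel, evaluated on a regular
#' grid spanning the data range extended by three bandwidths on each side.
#' The automatic bandwidth is Silverman's rule of thumb,
#' `0.9 * min(sd, IQR/1.34) * n^(-1/5)`, which requires at least two
#' distinct values; pass `bandwidth` explicitly otherwise.
#'
#' @param values Numeric vector; missing values are ignored.
#' @param bandwidth Kernel standard deviation; `NULL` for Silverman's rule.
#' @param n_grid Number of grid points (default 256).
#' @param grid Explicit evaluation points, overriding the automatic grid
#'   (e.g. to read the density off at the observations themselves).
#' @return A `density_curve` with `grid`, `density`, `bandwidth` and `n`.
#' @export
kde <- function(values, bandwidth = NULL, n_grid = 256, grid = NULL) {
  values <- drop_missing(values)
  n <- length(values)
  if (n == 0) {
    sm_abort("sm_analytics_error", "kde requires at least one finite value")
  }
  if (is.null(bandwidth)) {
    if (length(unique(values)) < 2) {
      sm_abort("sm_analytics_error",
               "automatic bandwidth requires >= 2 distinct values; supply `bandwidth`")
    }
    iqr <- unname(diff(quantile(values, c(0.25, 0.75), type = 7)))
    bandwidth <- 0.9 * min(sd(values), iqr / 1.34) * n^(-1 / 5)
  }
  bandwidth <- as.numeric(bandwidth)
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    sm_abort("sm_analytics_error",
             sprintf("bandwidth must be positive and finite, got %s", bandwidth))
  }
  if (is.null(grid)) {
    grid <- seq(min(values) - 3 * bandwidth, max(values) + 3 * bandwidth,
                length.out = n_grid)
  }
  n_grid <- length(grid)
  # exact mixture evaluation, chunked to bound memory at large n
  dens <- numeric(n_grid)
  chunk <- max(1L, as.integer(ceiling(2e6 / n)))
  for (start in seq(1, n_grid, by = chunk)) {
    ix <- start:min(start + chunk - 1, n_grid)
    dens[ix] <- rowMeans(dnorm(outer(grid[ix], values, "-"), sd = bandwidth))
  }
  structure(list(grid = grid, density = dens, bandwidth = bandwidth, n = n),
            class = "density_curve")
}

#' @export
print.density_curve <- function(x, ...) {
  cat(sprintf("<density_curve> n=%d bandwidth=%.4g grid=%d points\n",
              x$n, x$bandwidth, length(x$grid)))
  invisible(x)
}

#' Ordinary least-squares regression line
#'
#' Fits `y ~ x` on the coordinates as displayed (i.e. after any axis
#' transform applied by the query). `r_squared = 1 - SS_res/SS_tot`; when
#' the response is constant (`SS_tot = 0`) the fit is flagged degenerate and
#' `r_squared` is reported as 0.
#'
#' @param points A `point_set` with `x` and `y` columns, or any data frame
#'   with numeric `x` and `y`.
#' @return A `regression_fit` with `slope`, `intercept`, `r_squared`,
#'   `slope_se`, `n_points` and `degenerate`. Supports [tidy()] and
#'   [glance()].
#' @export
fit_regression <- function(points) {
  if (!is.data.frame(points) || !all(c("x", "y") %in% names(points))) {
    sm_abort("sm_analytics_error", "fit_regression needs a data frame with x and y")
  }
  ok <- !is.na(points$x) & !is.na(points$y)
  x <- points$x[ok]; y <- points$y[ok]
  if (length(x) < 2) {
    sm_abort("sm_analytics_error", "regression requires at least 2 complete points")
  }
  if (length(unique(x)) < 2) {
    sm_abort("sm_analytics_error",
             "all x values are equal (vertical line); cannot fit y ~ x")
  }
  fit <- lm(y ~ x)
  cf <- coef(fit)
  res <- stats::residuals(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  degenerate <- ss_tot == 0
  r2 <- if (degenerate) 0 else 1 - ss_res / ss_tot
  se <- tryCatch(suppressWarnings(summary(fit))$coefficients[, "Std. Error"],
                 error = function(e) c(NA_real_, NA_real_))
  structure(list(
    slope = unname(cf[["x"]]), intercept = unname(cf[["(Intercept)"]]),
    r_squared = r2, slope_se = unname(se[["x"]]),
    intercept_se = unname(se[["(Intercept)"]]),
    n_points = length(x), degenerate = degenerate
  ), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> y = %.4g x + %.4g  (r^2 = %.4f, n = %d%s)\n",
              x$slope, x$intercept, x$r_squared, x$n_points,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' @method tidy regression_fit
#' @export
tidy.regression_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "x"),
         estimate = c(x$intercept, x$slope),
         std.error = c(x$intercept_se, x$slope_se))
}

#' @method glance regression_fit
#' @export
glance.regression_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = x$n_points, degenerate = x$degenerate)
}

#' Compare two point sets
#'
#' Puts two query results (same level, same axis features) side by side:
#' shared axis ranges (union of per-set ranges) and per-axis summary
#' statistics with their differences (`b - a`).
#'
#' @param a,b `point_set`s with matching level and axis features.
#' @return A `plot_comparison`: `shared_range`, a `summary` tibble (set,
#'   axis, n, mean, sd, min, max) and a `delta` tibble (axis, mean_diff).
#' @export
compare_plots <- function(a, b) {
  stopifnot(inherits(a, "point_set"), inherits(b, "point_set"))
  sa <- attr(a, "state"); sb <- attr(b, "state")
  if (!identical(attr(a, "level"), attr(b, "level"))) {
    sm_abort("sm_analytics_error", "cannot compare point sets at different levels")
  }
  same_axes <- identical(sa$x_feature, sb$x_feature) &&
    identical(sa$y_feature, sb$y_feature)
  if (!same_axes) {
    sm_abort("sm_analytics_error",
             "cannot compare point sets with different axis features")
  }
  axes <- c("x", if (all(c("y") %in% names(a)) && "y" %in% names(b)) "y")
  summarise_set <- function(ps, label) {
    dplyr::bind_rows(lapply(axes, function(ax) {
      v <- ps[[ax]]
      tibble(set = label, axis = ax, n = length(v),
             mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_,
             min = if (length(v)) min(v) else NA_real_,
             max = if (length(v)) max(v) else NA_real_)
    }))
  }
  summary <- dplyr::bind_rows(summarise_set(a, "a"), summarise_set(b, "b"))
  delta <- dplyr::bind_rows(lapply(axes, function(ax) {
    tibble(axis = ax,
           mean_diff = mean(b[[ax]]) - mean(a[[ax]]))
  }))
  shared_range <- lapply(stats::setNames(axes, axes), function(ax) {
    range(c(a[[ax]], b[[ax]]))
  })
  structure(list(level = attr(a, "level"),
                 x_feature = sa$x_feature, y_feature = sa$y_feature,
                 shared_range = shared_range, summary = summary, delta = delta),
            class = "plot_comparison")
}

#' @export
print.plot_comparison <- function(x, ...) {
  cat(sprintf("<plot_comparison> level=%s x=%s%s\n", x$level, x$x_feature,
              if (is.null(x$y_feature)) "" else paste0(" y=", x$y_feature)))
  print(x$summary)
  invisible(x)
}
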