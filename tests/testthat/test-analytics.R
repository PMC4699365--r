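# Analytics toolkit: histograms, KDE, regression, comparison.

test_that("histogram follows the right-open/last-closed binning convention", {
  h <- histogram(c(0, 0.5, 1), bins = 2)
  expect_equal(h$bin_edges, c(0, 0.5, 1))
  expect_equal(h$counts[[1]], c(1L, 2L))

  h <- histogram(c(3, 3, 3))
  expect_equal(h$bin_edges, c(2.5, 3.5))
  expect_equal(h$counts[[1]], 3L)

  expect_error(histogram(numeric()), class = "sm_analytics_error")
  expect_error(histogram(c(NA, NA)), class = "sm_analytics_error")
})

test_that("histogram counts match an independent binning script and conserve n", {
  withr::with_seed(7, {
    x <- runif(1000)
    h <- histogram(x, bins = 10)
    # independent oracle: explicit interval membership per bin
    oracle <- vapply(seq_len(10), function(b) {
      lo <- h$bin_edges[b]; hi <- h$bin_edges[b + 1]
      if (b < 10) sum(x >= lo & x < hi) else sum(x >= lo & x <= hi)
    }, numeric(1))
    expect_identical(as.numeric(h$counts[[1]]), oracle)
    expect_equal(sum(h$counts[[1]]), 1000)
    # default bin count: Sturges
    expect_equal(length(histogram(x)$bin_edges) - 1, ceiling(log2(1000)) + 1)
  })
})

test_that("multihistogram shares edges over the pooled range", {
  h <- multihistogram(list(a = c(0, 1), b = c(2, 3)), bins = 2)
  expect_equal(h$bin_edges, c(0, 1.5, 3))
  expect_equal(h$counts$a, c(2L, 0L))
  expect_equal(h$counts$b, c(0L, 2L))
  h2 <- multihistogram(list(p = c(1, 2, 5), q = c(1, 2, 5)), bins = 3)
  expect_identical(h2$counts$p, h2$counts$q)
  expect_error(multihistogram(list(a = 1, bad = numeric())),
               class = "sm_analytics_error")
  expect_equal(vapply(h2$counts, sum, integer(1)), c(p = 3L, q = 3L))
})

test_that("multihistogram separates hit and non-hit populations in the planted direction", {
  s <- small_screen(n_genes = 12, cells_per_gene = 40, n_features = 2,
                    n_hits = 4, effect_size = 2, seed = 71)
  dd <- run_query(s$graph, query_state("descriptive", "f01"))
  is_hit <- dd$group.geneID %in% s$truth$hit_genes
  h <- multihistogram(list(hit = dd$x[is_hit], other = dd$x[!is_hit]), bins = 12)
  mids <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
  centre <- function(cnt) sum(mids * cnt) / sum(cnt)
  # planted shift is positive: the hit mass centre must sit higher
  expect_gt(centre(h$counts$hit), centre(h$counts$other))
})

test_that("kde matches the closed-form Gaussian peak and normalizes", {
  h <- 0.7
  d <- kde(5, bandwidth = h, grid = 5)
  expect_equal(d$density, 1 / (h * sqrt(2 * pi)), tolerance = 1e-12)

  withr::with_seed(8, {
    x <- rnorm(500)
    d <- kde(x)
    integral <- sum(diff(d$grid) * (d$density[-1] + d$density[-256]) / 2)
    expect_gte(integral, 0.99)
    expect_lte(integral, 1.01)
    expect_true(all(d$density >= 0))
  })
  expect_error(kde(numeric()), class = "sm_analytics_error")
  expect_error(kde(c(1, 1, 1)), class = "sm_analytics_error")
  expect_error(kde(1:5, bandwidth = -1), class = "sm_analytics_error")
})

test_that("kde is shift-equivariant and tracks stats::density cross-check", {
  withr::with_seed(9, {
    x <- rnorm(200)
    d0 <- kde(x, bandwidth = 0.4)
    d1 <- kde(x + 3, bandwidth = 0.4)
    expect_equal(d1$grid, d0$grid + 3, tolerance = 1e-9)
    expect_equal(d1$density, d0$density, tolerance = 1e-9)
    # independent implementation (binned FFT) as a looser cross-check
    ref <- stats::density(x, bw = 0.4, kernel = "gaussian",
                          from = min(d0$grid), to = max(d0$grid), n = 256)
    expect_lt(max(abs(ref$y - d0$density)), 1e-3)
  })
})

test_that("regression recovers exact lines and flags degeneracy", {
  pts <- tibble::tibble(x = 0:3, y = 2 * (0:3) + 1)
  fit <- fit_regression(pts)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_points, 4)

  flat <- fit_regression(tibble::tibble(x = 1:4, y = rep(5, 4)))
  expect_equal(flat$slope, 0)
  expect_true(flat$degenerate)
  expect_equal(flat$r_squared, 0)

  expect_error(fit_regression(tibble::tibble(x = c(1, 1), y = c(1, 2))),
               class = "sm_analytics_error")
  expect_error(fit_regression(tibble::tibble(x = 1, y = 1)),
               class = "sm_analytics_error")
})

test_that("regression matches a normal-equations oracle on noisy data", {
  withr::with_seed(10, {
    x <- runif(200)
    y <- 3 * x + rnorm(200, sd = 0.1)
    fit <- fit_regression(tibble::tibble(x = x, y = y))
    # oracle: solve X'X b = X'y directly
    X <- cbind(1, x)
    b <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(fit$intercept, unname(b[1, 1]), tolerance = 1e-10)
    expect_equal(fit$slope, unname(b[2, 1]), tolerance = 1e-10)
    expect_gt(fit$slope, 2.9)
    expect_lt(fit$slope, 3.1)
  })
})

test_that("r-squared is invariant under affine rescaling of both axes", {
  withr::with_seed(12, {
    x <- rnorm(50); y <- 1.3 * x + rnorm(50, sd = 0.5)
    r2 <- fit_regression(tibble::tibble(x = x, y = y))$r_squared
    r2s <- fit_regression(tibble::tibble(x = 10 * x - 4, y = -2 * y + 7))$r_squared
    expect_equal(r2, r2s, tolerance = 1e-12)
  })
})

test_that("plot comparison reports deltas and shared ranges", {
  g <- toy_graph()
  a <- run_query(g, query_state("descriptive", "len", "width"))
  cmp <- compare_plots(a, a)
  expect_equal(cmp$delta$mean_diff, c(0, 0))

  b <- a
  b$x <- b$x + 1
  cmp <- compare_plots(a, b)
  expect_equal(cmp$delta$mean_diff[cmp$delta$axis == "x"], 1)
  expect_equal(cmp$shared_range$x, range(c(a$x, b$x)))

  filt <- run_query(g, query_state(
    "descriptive", "len", "width",
    filters = list(range_filter("Cell", "len", 0, 3))))
  cmp <- compare_plots(filt, a)
  n <- cmp$summary
  expect_lte(n$n[n$set == "a"][1], n$n[n$set == "b"][1])
  expect_true(all(filt$x %in% a$x))   # filtered set is a subset

  other <- run_query(g, query_state("descriptive", "width", "len"))
  expect_error(compare_plots(a, other), class = "sm_analytics_error")
})
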