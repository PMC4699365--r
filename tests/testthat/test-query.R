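# Multi-level query engine: aggregation, filtering, transforms, selection
# and drill-down.

test_that("aggregate_feature computes per-gene summaries", {
  g <- toy_graph()
  agg <- aggregate_feature(g, "len", "mean")
  expect_equal(agg$value[agg$geneID == "g1"], 2)
  cnt <- aggregate_feature(g, "width", "count")
  # g2 has one missing width of 2 cells
  expect_equal(cnt$value[cnt$geneID == "g2"], 1)
  expect_error(aggregate_feature(g, "nope"), class = "sm_query_error")
})

test_that("aggregation agrees with brute-force per-group recomputation", {
  s <- small_screen(n_genes = 20, cells_per_gene = 11, n_features = 3,
                    n_hits = 3, seed = 21)
  raw <- read.csv(s$paths$data, skip = 3, header = FALSE,
                  colClasses = "character")
  names(raw) <- strsplit(readLines(s$paths$data, n = 1), ",")[[1]]
  raw$f02 <- as.numeric(raw$f02)
  for (method in c("mean", "median", "count", "min", "max")) {
    agg <- aggregate_feature(s$graph, "f02", method)
    brute <- vapply(split(raw$f02, raw$geneID), function(v) {
      v <- v[!is.na(v)]
      switch(method, mean = mean(v), median = median(v),
             count = as.numeric(length(v)), min = min(v), max = max(v))
    }, numeric(1))
    expect_equal(stats::setNames(agg$value, agg$geneID),
                 brute[order(names(brute))],
                 tolerance = if (method == "mean") 1e-12 else 0)
  }
})

test_that("run_query at grouping level aggregates and filters by label", {
  g <- toy_graph()
  ps <- run_query(g, query_state("grouping", "len", "width"))
  expect_equal(nrow(ps), 2)
  expect_equal(ps$x[ps$geneID == "g1"], 2)     # mean of 1,2,3
  expect_equal(ps$y[ps$geneID == "g2"], 40)    # one non-missing width
  ps <- run_query(g, query_state("grouping", "len", "width",
                                 filters = list(label_filter("Gene", "hit"))))
  expect_equal(ps$geneID, "g1")
  ps <- run_query(g, query_state(
    "grouping", "len", "width",
    filters = list(label_filter("Gene", "hit", present = FALSE))))
  expect_equal(ps$geneID, "g2")
})

test_that("random query states match a sequential data.table oracle", {
  s <- small_screen(n_genes = 15, cells_per_gene = 12, n_features = 4,
                    n_hits = 3, seed = 31)
  withr::with_seed(32, {
    for (i in 1:25) {
      st <- random_state(sprintf("f%02d", 1:4))
      got <- run_query(s$graph, st)
      want <- oracle_query(s$paths$data, s$paths$labels, st)
      expect_equal(nrow(got), nrow(want), info = state_to_json(st))
      if (nrow(got)) {
        expect_equal(got$x, want$x, tolerance = 1e-9, info = state_to_json(st))
        if (!is.null(st$y_feature)) {
          expect_equal(got$y, want$y, tolerance = 1e-9, info = state_to_json(st))
        }
      }
    }
  })
})

test_that("filters compose conjunctively, order-independently and monotonically", {
  s <- small_screen(n_genes = 10, cells_per_gene = 10, n_features = 2,
                    n_hits = 2, seed = 41)
  f1 <- range_filter("Cell", "f01", 8, 12)
  f2 <- label_filter("Gene", "hit", present = FALSE)
  f3 <- range_filter("Gene", "f02", 9, 11)
  base <- query_state("descriptive", "f01", "f02")
  n_unfiltered <- nrow(run_query(s$graph, base))
  perms <- list(list(f1, f2, f3), list(f3, f1, f2), list(f2, f3, f1))
  results <- lapply(perms, function(fl) {
    run_query(s$graph, query_state("descriptive", "f01", "f02", filters = fl))
  })
  expect_identical(ps_data(results[[1]]), ps_data(results[[2]]))
  expect_identical(ps_data(results[[1]]), ps_data(results[[3]]))
  # adding a filter never increases the record count
  n1 <- nrow(run_query(s$graph,
                       query_state("descriptive", "f01", "f02",
                                   filters = list(f1))))
  n12 <- nrow(run_query(s$graph,
                        query_state("descriptive", "f01", "f02",
                                    filters = list(f1, f2))))
  expect_lte(n1, n_unfiltered)
  expect_lte(n12, n1)
})

test_that("a selection covering the full range is a no-op", {
  s <- small_screen(n_genes = 8, cells_per_gene = 10, n_features = 2,
                    n_hits = 2, seed = 51)
  st0 <- query_state("descriptive", "f01", "f02")
  full <- run_query(s$graph, st0)
  st1 <- query_state("descriptive", "f01", "f02",
                     selection = list(x_min = min(full$x), x_max = max(full$x),
                                      y_min = min(full$y), y_max = max(full$y)))
  sel <- run_query(s$graph, st1)
  expect_equal(ps_data(sel), ps_data(full))
})

test_that("log10 transform applies after filtering and rejects non-positives", {
  g <- toy_graph()
  ps <- run_query(g, query_state("grouping", "len", x_transform = "log10"))
  expect_equal(sort(ps$x), sort(log10(c(2, 8.5))))
  add_node(g, "Cell", c(cellID = "neg"), list(len = -1, width = 1))
  connect(g, node_id_of(g, "Cell", c(cellID = "neg")),
          node_id_of(g, "Gene", c(geneID = "g1")), "MEMBER_OF")
  expect_error(
    run_query(g, query_state("descriptive", "len", x_transform = "log10")),
    class = "sm_transform_error"
  )
})

test_that("unknown features and labels are query errors", {
  g <- toy_graph()
  expect_error(run_query(g, query_state("descriptive", "nope")),
               class = "sm_query_error")
  expect_error(
    run_query(g, query_state("descriptive", "len",
                             filters = list(label_filter("Gene", "nolabel")))),
    class = "sm_query_error"
  )
})

test_that("drill-down expands gene selections into member cells", {
  g <- toy_graph()
  dd <- drill_down(g, "g1", "len", "width")
  expect_equal(nrow(dd), 3)
  expect_true(all(dd$group.geneID == "g1"))
  expect_equal(nrow(drill_down(g, character(), "len")), 0)
  expect_error(drill_down(g, "ghost", "len"), class = "sm_missing_node_error")

  s <- small_screen(n_genes = 6, cells_per_gene = 9, n_features = 2,
                    n_hits = 1, seed = 61)
  sel_genes <- c("gene002", "gene005")
  dd <- drill_down(s$graph, sel_genes, "f01")
  # counting oracle: per-gene cell counts from the generator's design
  expect_equal(nrow(dd), 2 * s$truth$cells_per_gene)
})

test_that("list_catalog returns sorted features and labels", {
  g <- toy_graph()
  expect_equal(list_catalog(g, "Cell")$features, c("len", "width"))
  expect_equal(list_catalog(g, "Gene")$labels, "hit")
  expect_equal(list_catalog(g, "Image")$features, character())
  expect_error(list_catalog(g, "Nope"), class = "sm_query_error")
})
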