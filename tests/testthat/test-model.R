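# Property-graph store: node/edge bookkeeping, ownership traversal, label
# semantics and serialization.

test_that("nodes are retrievable by external identity and counted per kind", {
  g <- property_graph()
  register_kind(g, "Gene", role = "grouping")
  register_kind(g, "Cell", role = "descriptive")
  add_node(g, "Gene", c(gene = "abc1"))
  expect_equal(node_count(g, "Gene"), 1)
  expect_false(is.null(node_id_of(g, "Gene", c(gene = "abc1"))))
  add_node(g, "Cell", c(cellID = "c1"))
  add_node(g, "Cell", c(cellID = "c2"))
  expect_equal(node_count(g, "Cell"), 2)
  expect_error(add_node(g, "Gene", c(gene = "abc1")),
               class = "sm_duplicate_object_error")
  expect_error(add_node(g, "Strain", c(s = "x")), class = "sm_schema_error")
})

test_that("feature catalog equals a brute-force scan of stored numeric properties", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      g <- property_graph()
      register_kind(g, "Gene", role = "grouping")
      register_kind(g, "Cell", role = "descriptive")
      all_props <- paste0("p", 1:6)
      expected <- character()
      for (i in 1:20) {
        props <- list()
        for (p in sample(all_props, sample(0:4, 1))) {
          if (runif(1) < 0.7) {
            props[[p]] <- rnorm(1)
            expected <- union(expected, p)
          } else {
            props[[p]] <- paste0("txt", i)
          }
        }
        add_node(g, "Cell", c(cellID = paste0("c", i)), props)
      }
      # brute force over the stored nodes themselves
      brute <- character()
      for (nid in ls(g$nodes, all.names = TRUE)) {
        nd <- g$nodes[[nid]]
        brute <- union(brute, names(nd$properties)[
          vapply(nd$properties, is.numeric, logical(1))])
      }
      expect_setequal(list_catalog(g, "Cell")$features, brute)
      expect_setequal(brute, expected)
    }
  })
})

test_that("edges are idempotent and traversable", {
  g <- property_graph()
  register_kind(g, "Gene", role = "grouping")
  register_kind(g, "Cell", role = "descriptive")
  register_kind(g, "Image", role = "metadata")
  gene <- add_node(g, "Gene", c(id = "g"))
  cell <- add_node(g, "Cell", c(id = "c"))
  img <- add_node(g, "Image", c(id = "im"))
  connect(g, cell, img, "DERIVED_FROM")
  expect_equal(neighbors_of(g, cell), img)
  connect(g, cell, img, "DERIVED_FROM")
  expect_equal(edge_count(g), 1)
  connect(g, img, gene, "MEMBER_OF")
  expect_equal(owning_group(g, cell), gene)
  expect_error(connect(g, cell, "n999", "X"), class = "sm_missing_node_error")
})

test_that("owning_group resolves multi-hop paths and rejects ambiguity", {
  g <- property_graph()
  register_kind(g, "Gene", role = "grouping")
  register_kind(g, "Cell", role = "descriptive")
  register_kind(g, "Image", role = "metadata")
  register_kind(g, "Well", role = "metadata")
  gene <- add_node(g, "Gene", c(id = "g"))
  well <- add_node(g, "Well", c(id = "w"))
  img <- add_node(g, "Image", c(id = "im"))
  cell <- add_node(g, "Cell", c(id = "c"))
  connect(g, cell, img, "DERIVED_FROM")
  connect(g, img, well, "DERIVED_FROM")
  connect(g, well, gene, "MEMBER_OF")
  # breadth-first oracle on this toy: the only Gene reachable is `gene`
  expect_equal(owning_group(g, cell), gene)

  orphan <- add_node(g, "Cell", c(id = "lonely"))
  expect_error(owning_group(g, orphan), class = "sm_graph_integrity_error")

  gene2 <- add_node(g, "Gene", c(id = "g2"))
  connect(g, cell, gene2, "MEMBER_OF")
  expect_error(owning_group(g, cell), class = "sm_graph_integrity_error")
})

test_that("label assignment follows binary semantics", {
  g <- toy_graph()
  nd <- set_labels(g, "Gene", c(geneID = "g2"),
                   c(hit_shape = 1, hit_cycle = 0))
  expect_equal(nd$labels, "hit_shape")
  nd <- set_labels(g, "Gene", c(geneID = "g2"),
                   c(hit_shape = 0, hit_cycle = 0))
  expect_equal(nd$labels, character())
  expect_error(set_labels(g, "Gene", c(geneID = "g2"), c(hit = 2)),
               class = "sm_label_value_error")
  expect_true(all(c("hit_shape", "hit_cycle") %in% list_catalog(g, "Gene")$labels))
})

test_that("serialization round-trips nodes, edges, properties and labels", {
  g <- toy_graph()
  # awkward values: exact decimal round trip required
  add_node(g, "Cell", c(cellID = "c6"),
           list(len = 0.1 + 0.2, width = 1e-3))
  f <- withr::local_tempfile()
  write_graph(g, f)
  g2 <- read_graph(f)
  for (k in c("Gene", "Cell", "Image")) {
    expect_equal(node_count(g2, k), node_count(g, k))
  }
  expect_equal(edge_count(g2), edge_count(g))
  c6 <- g2$nodes[[node_id_of(g2, "Cell", c(cellID = "c6"))]]
  expect_identical(c6$properties$len, 0.1 + 0.2)
  expect_identical(c6$properties$width, 1e-3)
  g1n <- g2$nodes[[node_id_of(g2, "Gene", c(geneID = "g1"))]]
  expect_equal(g1n$labels, "hit")
  # second serialization is byte-identical (stable ordering)
  f2 <- withr::local_tempfile()
  write_graph(g2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("merging rows into an existing node fills but never contradicts", {
  g <- property_graph()
  register_kind(g, "Gene", role = "grouping")
  add_node(g, "Gene", c(id = "g"), list(score = 1.5, note = "a"))
  add_node(g, "Gene", c(id = "g"), list(score = 1.5, extra = "b"),
           on_duplicate = "merge")
  nd <- g$nodes[[node_id_of(g, "Gene", c(id = "g"))]]
  expect_equal(nd$properties$extra, "b")
  expect_error(
    add_node(g, "Gene", c(id = "g"), list(score = 2), on_duplicate = "merge"),
    class = "sm_import_conflict_error"
  )
})
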