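# Screen-CSV importer: schema parsing, graph construction, label import and
# file validation.

test_that("parse_schema reads the three header rows and normalizes types", {
  rows <- list(c("geneID", "cellID", "length"),
               c("Gene", "Cell", "Cell"),
               c("ID", "ID", "NUMBER"))
  schema <- parse_schema(rows, grouping = "Gene", descriptive = "Cell")
  expect_equal(nrow(schema), 3)
  expect_equal(schema$object[3], "Cell")
  expect_equal(schema$ptype[3], "NUMBER")
  expect_equal(attr(schema, "grouping"), "Gene")

  rows[[3]] <- c("id", "Id", "number")   # case-insensitive tokens
  schema <- parse_schema(rows, grouping = "Gene", descriptive = "Cell")
  expect_equal(schema$ptype, c("ID", "ID", "NUMBER"))

  rows[[3]] <- c("ID", "ID", "FLOAT")
  expect_error(parse_schema(rows), class = "sm_format_error")
  expect_error(parse_schema(rows[1:2]), class = "sm_format_error")
  expect_error(parse_schema(list(c("a", "b"), c("G", "G"), c("ID", "NUMBER", "X"))),
               class = "sm_format_error")
})

test_that("default role heuristic picks first-ID object and most-NUMBER object", {
  rows <- list(c("geneID", "cellID", "len", "width"),
               c("Gene", "Cell", "Cell", "Cell"),
               c("ID", "ID", "NUMBER", "NUMBER"))
  schema <- parse_schema(rows)
  expect_equal(attr(schema, "grouping"), "Gene")
  expect_equal(attr(schema, "descriptive"), "Cell")
})

test_that("objects without an ID column are rejected", {
  rows <- list(c("geneID", "len"), c("Gene", "Cell"), c("ID", "NUMBER"))
  expect_error(parse_schema(rows), class = "sm_format_error")
})

test_that("import builds one node per distinct ID tuple and links rows", {
  rows <- list(c("geneID", "cellID", "length"),
               c("Gene", "Cell", "Cell"),
               c("ID", "ID", "NUMBER"))
  schema <- parse_schema(rows, grouping = "Gene", descriptive = "Cell")
  data <- rbind(c("g1", "c1", "1.5"),
                c("g1", "c2", "2.5"),
                c("g2", "c3", "1e-3"),
                c("g2", "c4", ""))
  g <- import_screen(data, schema)
  # oracle: distinct ID tuples per object, counted independently
  expect_equal(node_count(g, "Gene"), length(unique(data[, 1])))
  expect_equal(node_count(g, "Cell"), length(unique(data[, 2])))
  expect_equal(edge_count(g), 4)
  c3 <- g$nodes[[node_id_of(g, "Cell", c(cellID = "c3"))]]
  expect_identical(c3$properties$length, 1e-3)
  c4 <- g$nodes[[node_id_of(g, "Cell", c(cellID = "c4"))]]
  expect_true(is.na(c4$properties$length))
  expect_equal(owning_group(g, node_id_of(g, "Cell", c(cellID = "c1"))),
               node_id_of(g, "Gene", c(geneID = "g1")))
})

test_that("empty data imports to an empty graph with registered kinds", {
  rows <- list(c("geneID", "cellID", "len"),
               c("Gene", "Cell", "Cell"),
               c("ID", "ID", "NUMBER"))
  schema <- parse_schema(rows, grouping = "Gene", descriptive = "Cell")
  g <- import_screen(matrix(character(), 0, 3), schema)
  expect_equal(node_count(g, "Gene"), 0)
  expect_equal(node_count(g, "Cell"), 0)
  expect_equal(sort(graph_kinds(g)$name), c("Cell", "Gene"))
})

test_that("unparseable NUMBER cells fail with file coordinates", {
  rows <- list(c("geneID", "cellID", "len"),
               c("Gene", "Cell", "Cell"),
               c("ID", "ID", "NUMBER"))
  schema <- parse_schema(rows, grouping = "Gene", descriptive = "Cell")
  data <- rbind(c("g1", "c1", "1.5"), c("g1", "c2", "abc"))
  err <- expect_error(import_screen(data, schema), class = "sm_import_error")
  expect_match(conditionMessage(err), "row 5")
  expect_match(conditionMessage(err), "column 3")
})

test_that("label import matches grouping nodes and counts annotations", {
  g <- toy_graph()
  set_labels(g, "Gene", c(geneID = "g1"), c(hit = 0))  # reset fixture label
  n <- import_labels(g, rbind(c("g1", "1"), c("g2", "0")),
                     n_id_columns = 1, label_names = "hit")
  expect_equal(as.integer(n), 1)
  g1 <- g$nodes[[node_id_of(g, "Gene", c(geneID = "g1"))]]
  expect_true("hit" %in% g1$labels)

  n <- import_labels(g, rbind(c("g1", "0"), c("g2", "0")),
                     n_id_columns = 1, label_names = "other")
  expect_equal(as.integer(n), 0)

  expect_warning(
    n <- import_labels(g, rbind(c("g1", "1"), c("g2", "1"), c("ghost", "1")),
                       n_id_columns = 1, label_names = "hit"),
    class = "sm_unknown_group_warning"
  )
  expect_equal(as.integer(n), 2)
  expect_length(attr(n, "unknown"), 1)
  expect_error(
    import_labels(g, rbind(c("g1", "2")), n_id_columns = 1, label_names = "hit"),
    class = "sm_label_value_error"
  )
})

test_that("import is deterministic: same file, identical serialized graph", {
  dir <- withr::local_tempdir()
  paths <- generate_screen(screen_truth(n_genes = 3, cells_per_gene = 4,
                                        n_features = 2, n_hits = 1, seed = 5),
                           dir)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_graph(read_screen(paths$data), f1)
  write_graph(read_screen(paths$data), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("import then full descriptive export reproduces numeric values", {
  s <- small_screen(n_genes = 4, cells_per_gene = 5, n_features = 3,
                    n_hits = 1, seed = 9)
  ps <- run_query(s$graph, query_state("descriptive", "f01", "f02"))
  csv <- export_csv(ps)
  re <- read.csv(text = csv, colClasses = "character")
  src <- read.csv(s$paths$data, skip = 3, header = FALSE,
                  colClasses = "character")
  names(src) <- strsplit(readLines(s$paths$data, n = 1), ",")[[1]]
  src <- src[order(src$cellID), ]
  expect_identical(as.numeric(re$f01), as.numeric(src$f01))
  expect_identical(as.numeric(re$f02), as.numeric(src$f02))
})

test_that("validate_screen_file reports coordinates and mirrors importability", {
  dir <- withr::local_tempdir()
  paths <- generate_screen(screen_truth(n_genes = 3, cells_per_gene = 4,
                                        n_features = 2, n_hits = 1, seed = 2),
                           dir)
  expect_equal(nrow(validate_screen_file(paths$data)), 0)

  bad <- generate_corrupted("bad-number-cell", withr::local_tempdir())
  report <- validate_screen_file(bad$data)
  expect_equal(nrow(report), 1)
  expect_equal(report$row, bad$row)
  expect_equal(report$column, bad$column)

  two_rows <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("geneID,len", "Gene,Gene"), two_rows)
  report <- validate_screen_file(two_rows)
  expect_match(report$issue, "missing property-type row")
})
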