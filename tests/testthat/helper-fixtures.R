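# Shared fixtures, built in code at test time.

# A hand-built toy graph: 2 genes, 5 cells with len/width features, one
# image per gene; g1 carries the "hit" label.
toy_graph <- function() {
  g <- property_graph()
  register_kind(g, "Gene", role = "grouping")
  register_kind(g, "Cell", role = "descriptive")
  register_kind(g, "Image", role = "metadata")
  g1 <- add_node(g, "Gene", c(geneID = "g1"))
  g2 <- add_node(g, "Gene", c(geneID = "g2"))
  i1 <- add_node(g, "Image", c(imageID = "im1"),
                 list(url = "https://images.example.org/im1.png"))
  i2 <- add_node(g, "Image", c(imageID = "im2"),
                 list(url = "https://images.example.org/im2.png"))
  cells <- list(
    list(id = "c1", gene = g1, img = i1, len = 1, width = 10),
    list(id = "c2", gene = g1, img = i1, len = 2, width = 20),
    list(id = "c3", gene = g1, img = i1, len = 3, width = 30),
    list(id = "c4", gene = g2, img = i2, len = 8, width = 40),
    list(id = "c5", gene = g2, img = i2, len = 9, width = NA_real_)
  )
  for (cl in cells) {
    nid <- add_node(g, "Cell", c(cellID = cl$id),
                    list(len = cl$len, width = cl$width))
    connect(g, nid, cl$gene, "MEMBER_OF")
    connect(g, nid, cl$img, "DERIVED_FROM")
  }
  set_labels(g, "Gene", c(geneID = "g1"), c(hit = 1))
  set_labels(g, "Gene", c(geneID = "g2"), c(hit = 0))
  g
}

# Generated screen imported into a graph, with truth and file paths.
small_screen <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                         ...) {
  truth <- screen_truth(...)
  paths <- generate_screen(truth, dir)
  graph <- read_screen(paths$data)
  suppressWarnings(import_labels_file(graph, paths$labels))
  list(graph = graph, paths = paths, truth = truth, dir = dir)
}

# Independent oracle for run_query: a literal sequential script over the
# raw CSV files in base R (filter cells, aggregate per gene, filter genes,
# transform, select), sharing no code with the graph/dplyr implementation.
oracle_query <- function(data_csv, labels_csv, state) {
  dt <- read.csv(data_csv, skip = 3, header = FALSE, colClasses = "character")
  names(dt) <- strsplit(readLines(data_csv, n = 1), ",", fixed = TRUE)[[1]]
  for (j in 5:ncol(dt)) dt[[j]] <- as.numeric(dt[[j]])
  lab <- read.csv(labels_csv, colClasses = c("character", "integer"))
  aggfun <- switch(state$aggregation,
                   mean = function(v) mean(v[!is.na(v)]),
                   median = function(v) stats::median(v[!is.na(v)]),
                   count = function(v) as.numeric(sum(!is.na(v))),
                   min = function(v) min(v[!is.na(v)]),
                   max = function(v) max(v[!is.na(v)]))
  per_gene <- function(d, feature) {
    vapply(split(d[[feature]], d$geneID), aggfun, numeric(1))
  }
  # step 1: descriptive-level filters
  for (cl in state$filters) {
    if (cl$kind == "Cell" && cl$type == "numeric_range") {
      v <- dt[[cl$property]]
      dt <- dt[!is.na(v) & v >= cl$low & v <= cl$high, , drop = FALSE]
    }
  }
  hit_genes <- lab$geneID[lab$hit == 1]
  # step 2: the set of genes allowed by grouping-level filters
  keep_gene <- unique(dt$geneID)
  for (cl in state$filters) {
    if (cl$kind == "Gene" && cl$type == "label_present") {
      keep_gene <- intersect(keep_gene, hit_genes)
    } else if (cl$kind == "Gene" && cl$type == "label_absent") {
      keep_gene <- setdiff(keep_gene, hit_genes)
    } else if (cl$kind == "Gene" && cl$type == "numeric_range") {
      agg <- per_gene(dt, cl$property)
      ok <- names(agg)[!is.na(agg) & agg >= cl$low & agg <= cl$high]
      keep_gene <- intersect(keep_gene, ok)
    }
  }
  # step 3: project the requested level
  if (state$level == "grouping") {
    xs <- per_gene(dt, state$x_feature)
    out <- data.frame(id = names(xs), x = unname(xs))
    if (!is.null(state$y_feature)) {
      ys <- per_gene(dt, state$y_feature)
      out$y <- unname(ys[out$id])
    }
    out <- out[out$id %in% keep_gene, , drop = FALSE]
  } else {
    dt <- dt[dt$geneID %in% keep_gene, , drop = FALSE]
    out <- data.frame(id = dt$cellID, x = dt[[state$x_feature]])
    if (!is.null(state$y_feature)) out$y <- dt[[state$y_feature]]
  }
  out <- out[!is.na(out$x), , drop = FALSE]
  if (!is.null(state$y_feature)) out <- out[!is.na(out$y), , drop = FALSE]
  if (state$x_transform == "log10") out$x <- log10(out$x)
  if (!is.null(state$y_feature) && state$y_transform == "log10") {
    out$y <- log10(out$y)
  }
  if (!is.null(state$selection)) {
    s <- state$selection
    keep <- rep(TRUE, nrow(out))
    if (!is.na(s$x_min)) keep <- keep & out$x >= s$x_min
    if (!is.na(s$x_max)) keep <- keep & out$x <= s$x_max
    if (!is.null(state$y_feature)) {
      if (!is.na(s$y_min)) keep <- keep & out$y >= s$y_min
      if (!is.na(s$y_max)) keep <- keep & out$y <= s$y_max
    }
    out <- out[keep, , drop = FALSE]
  }
  out[order(out$id, method = "radix"), , drop = FALSE]
}

# Random-but-seeded query states over a generated screen's catalogs.
random_state <- function(features, rng_state = NULL) {
  level <- sample(c("grouping", "descriptive"), 1)
  x <- sample(features, 1)
  y <- if (stats::runif(1) < 0.7) sample(features, 1) else NULL
  agg <- sample(c("mean", "median", "count", "min", "max"), 1)
  filters <- list()
  if (stats::runif(1) < 0.5) {
    f <- sample(features, 1)
    lo <- stats::runif(1, 4, 9)
    filters <- c(filters, list(range_filter("Cell", f, lo, lo + stats::runif(1, 1, 8))))
  }
  if (stats::runif(1) < 0.4) {
    filters <- c(filters, list(label_filter("Gene", "hit",
                                            present = stats::runif(1) < 0.5)))
  }
  if (stats::runif(1) < 0.3) {
    f <- sample(features, 1)
    filters <- c(filters, list(range_filter("Gene", f, 8, 12)))
  }
  selection <- NULL
  if (stats::runif(1) < 0.3 && !is.null(y)) {
    selection <- list(x_min = 5, x_max = 15, y_min = 5, y_max = 15)
  }
  query_state(level = level, x_feature = x, y_feature = y,
              aggregation = agg, filters = filters,
              selection = selection)
}

# point-set contents without provenance attributes, for comparisons
ps_data <- function(p) {
  d <- as.data.frame(p)
  attributes(d) <- attributes(d)[c("names", "row.names", "class")]
  rownames(d) <- NULL
  d
}
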