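# Deterministic synthetic-screen generator.
#
# Emulates a miniature gene-knockout imaging screen in the import dialect:
# genes (grouping), images (metadata, with placeholder URLs) and cells
# (descriptive) carrying independent Gaussian features. A subset of "hit"
# genes receives a planted mean shift, expressed in within-gene standard
# deviation units, and is marked 1 in the label file. All parameters and
# the drawn hit set are recorded in a truth JSON so every downstream module
# can be tested against known ground truth.

#' Describe a synthetic screen
#'
#' @param n_genes Number of genes (grouping objects).
#' @param cells_per_gene Cells (descriptive objects) per gene.
#' @param n_features Number of Gaussian NUMBER features per cell.
#' @param n_hits Number of hit genes carrying the planted effect.
#' @param effect_size Mean shift for hit genes, in units of the feature's
#'   within-gene standard deviation.
#' @param affected_features Indices of the features shifted in hit genes.
#' @param base_means,base_sds Per-feature baseline mean and standard
#'   deviation; recycled to `n_features`.
#' @param cells_per_image Cells per synthetic image (metadata granularity).
#' @param paired_slope When non-`NULL`, two extra cell features `pair_x`
#'   and `pair_y` are added with `pair_y = paired_slope * pair_x + noise`,
#'   giving regression tests a known planted slope.
#' @param paired_noise_sd Noise standard deviation of the paired relation.
#' @param seed Integer seed; the same truth always generates byte-identical
#'   files.
#' @return A `screen_truth` object (also records the drawn `hit_genes`).
#' @export
screen_truth <- function(n_genes = 50, cells_per_gene = 100, n_features = 10,
                         n_hits = 5, effect_size = 2,
                         affected_features = 1,
                         base_means = 10, base_sds = 2,
                         cells_per_image = 10,
                         paired_slope = NULL, paired_noise_sd = 0.1,
                         seed = 1) {
  if (n_genes < 1 || cells_per_gene < 1 || n_features < 1 ||
      n_hits < 0 || n_hits > n_genes || cells_per_image < 1) {
    sm_abort("sm_generation_error", "invalid synthetic-screen parameters")
  }
  if (any(!is.finite(effect_size)) || any(affected_features > n_features)) {
    sm_abort("sm_generation_error", "invalid effect specification")
  }
  base_means <- rep_len(as.numeric(base_means), n_features)
  base_sds <- rep_len(as.numeric(base_sds), n_features)
  if (any(base_sds <= 0)) {
    sm_abort("sm_generation_error", "base_sds must be positive")
  }
  genes <- sprintf("gene%03d", seq_len(n_genes))
  hit_genes <- withr::with_seed(seed, sort(sample(genes, n_hits)))
  structure(list(
    n_genes = n_genes, cells_per_gene = cells_per_gene,
    n_features = n_features, n_hits = n_hits,
    effect_size = effect_size, affected_features = as.integer(affected_features),
    base_means = base_means, base_sds = base_sds,
    cells_per_image = cells_per_image,
    paired_slope = paired_slope, paired_noise_sd = paired_noise_sd,
    seed = as.integer(seed), genes = genes, hit_genes = hit_genes
  ), class = "screen_truth")
}

#' @export
print.screen_truth <- function(x, ...) {
  cat(sprintf(
    "<screen_truth> %d genes x %d cells x %d features; %d hits (effect %.2g sd), seed %d\n",
    x$n_genes, x$cells_per_gene, x$n_features, x$n_hits, x$effect_size, x$seed))
  invisible(x)
}

feature_names <- function(truth) {
  c(sprintf("f%02d", seq_len(truth$n_features)),
    if (!is.null(truth$paired_slope)) c("pair_x", "pair_y"))
}

# the full screen as in-memory tables; deterministic under truth$seed
synth_tables <- function(truth) {
  withr::with_seed(truth$seed, {
    hit_check <- sort(sample(truth$genes, truth$n_hits))
    stopifnot(identical(hit_check, truth$hit_genes))
    n_cells <- truth$n_genes * truth$cells_per_gene
    gene <- rep(truth$genes, each = truth$cells_per_gene)
    cell <- sprintf("cell%06d", seq_len(n_cells))
    img_idx <- rep(
      ceiling(seq_len(truth$cells_per_gene) / truth$cells_per_image),
      times = truth$n_genes
    )
    image <- sprintf("%s_img%02d", gene, img_idx)
    url <- paste0("https://images.example.org/synthetic/", image, ".png")
    feats <- matrix(NA_real_, nrow = n_cells, ncol = truth$n_features)
    is_hit_cell <- gene %in% truth$hit_genes
    for (f in seq_len(truth$n_features)) {
      shift <- ifelse(is_hit_cell & f %in% truth$affected_features,
                      truth$effect_size * truth$base_sds[f], 0)
      feats[, f] <- stats::rnorm(n_cells,
                                 mean = truth$base_means[f] + shift,
                                 sd = truth$base_sds[f])
    }
    colnames(feats) <- sprintf("f%02d", seq_len(truth$n_features))
    out <- tibble(geneID = gene, imageID = image, imageURL = url,
                  cellID = cell)
    out <- dplyr::bind_cols(out, as_tibble(feats))
    if (!is.null(truth$paired_slope)) {
      px <- stats::rnorm(n_cells)
      py <- truth$paired_slope * px +
        stats::rnorm(n_cells, sd = truth$paired_noise_sd)
      out$pair_x <- px
      out$pair_y <- py
    }
    labels <- tibble(geneID = truth$genes,
                     hit = as.integer(truth$genes %in% truth$hit_genes))
    list(data = out, labels = labels)
  })
}

#' Generate a synthetic screen on disk
#'
#' Writes three files into `out_dir`: `screen.csv` in the three-header-row
#' import dialect (objects Gene/Image/Cell), `labels.csv` marking hit genes
#' with 1, and `truth.json` recording every generation parameter including
#' the drawn hit genes. Identical truth objects produce byte-identical
#' files.
#'
#' @param truth A [screen_truth()].
#' @param out_dir Output directory (created if needed).
#' @return Named list of paths: `data`, `labels`, `truth`.
#' @export
generate_screen <- function(truth, out_dir) {
  stopifnot(inherits(truth, "screen_truth"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- synth_tables(truth)
  fn <- feature_names(truth)
  header1 <- c("geneID", "imageID", "imageURL", "cellID", fn)
  header2 <- c("Gene", "Image", "Image", "Cell", rep("Cell", length(fn)))
  header3 <- c("ID", "ID", "URL", "ID", rep("NUMBER", length(fn)))
  num_cols <- lapply(fn, function(f) num_repr(tabs$data[[f]]))
  data_lines <- do.call(paste, c(
    list(tabs$data$geneID, tabs$data$imageID, tabs$data$imageURL,
         tabs$data$cellID),
    num_cols, list(sep = ",")
  ))
  data_path <- file.path(out_dir, "screen.csv")
  write_lines_binary(c(paste(header1, collapse = ","),
                       paste(header2, collapse = ","),
                       paste(header3, collapse = ","),
                       data_lines), data_path)
  label_path <- file.path(out_dir, "labels.csv")
  write_lines_binary(c("geneID,hit",
                       paste(tabs$labels$geneID, tabs$labels$hit, sep = ",")),
                     label_path)
  truth_path <- file.path(out_dir, "truth.json")
  write_lines_binary(canonical_json(list(
    n_genes = truth$n_genes, cells_per_gene = truth$cells_per_gene,
    n_features = truth$n_features, n_hits = truth$n_hits,
    effect_size = truth$effect_size,
    affected_features = as.list(truth$affected_features),
    base_means = as.list(truth$base_means),
    base_sds = as.list(truth$base_sds),
    cells_per_image = truth$cells_per_image,
    paired_slope = truth$paired_slope,
    paired_noise_sd = truth$paired_noise_sd,
    seed = truth$seed,
    hit_genes = as.list(truth$hit_genes)
  )), truth_path)
  list(data = data_path, labels = label_path, truth = truth_path)
}

write_lines_binary <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

CORRUPTION_VARIANTS <- c("missing-type-row", "bad-number-cell",
                         "unknown-label-id", "ragged-row")

#' Generate a fixture exhibiting exactly one known defect
#'
#' Builds a small valid screen, then injects a single defect of the chosen
#' kind at a recorded coordinate, for exercising the validator and the
#' importer's error reporting.
#'
#' @param variant One of `"missing-type-row"`, `"bad-number-cell"`,
#'   `"unknown-label-id"`, `"ragged-row"`.
#' @param out_dir Output directory.
#' @param seed Seed for the underlying screen.
#' @return List with `data`, `labels`, `variant` and the 1-based `row` (and
#'   `column` where applicable) of the injected defect. Rows are file rows
#'   (data begins at row 4); for `"unknown-label-id"` the row indexes the
#'   label file.
#' @export
generate_corrupted <- function(variant = CORRUPTION_VARIANTS, out_dir, seed = 1) {
  variant <- match.arg(variant)
  truth <- screen_truth(n_genes = 3, cells_per_gene = 5, n_features = 2,
                        n_hits = 1, seed = seed)
  paths <- generate_screen(truth, out_dir)
  data_lines <- readLines(paths$data)
  label_lines <- readLines(paths$labels)
  row <- NA_integer_
  column <- NA_integer_
  if (variant == "missing-type-row") {
    data_lines <- data_lines[-3]
    row <- 3L
  } else if (variant == "bad-number-cell") {
    row <- 7L       # fourth data row
    column <- 5L    # first NUMBER column
    fields <- strsplit(data_lines[row], ",", fixed = TRUE)[[1]]
    fields[column] <- "abc"
    data_lines[row] <- paste(fields, collapse = ",")
  } else if (variant == "ragged-row") {
    row <- 6L
    fields <- strsplit(data_lines[row], ",", fixed = TRUE)[[1]]
    data_lines[row] <- paste(fields[-length(fields)], collapse = ",")
  } else if (variant == "unknown-label-id") {
    row <- 3L       # second label data row
    fields <- strsplit(label_lines[row], ",", fixed = TRUE)[[1]]
    fields[1] <- "ghost999"
    label_lines[row] <- paste(fields, collapse = ",")
  }
  write_lines_binary(data_lines, paths$data)
  write_lines_binary(label_lines, paths$labels)
  list(data = paths$data, labels = paths$labels, variant = variant,
       row = row, column = column)
}
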