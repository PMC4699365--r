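# Reproducibility surface: raw-data CSV export, SVG plot export and
# self-contained share tokens that serialize a complete query state into a
# URL-safe string.

csv_field <- function(x) {
  need_quote <- grepl('[",\n\r]', x)
  x[need_quote] <- paste0('"', gsub('"', '""', x[need_quote]), '"')
  x
}

#' Export a point set as CSV text
#'
#' RFC 4180 dialect, symmetric with the importer. The header row holds the
#' entity ID column names, the x/y feature names and (for descriptive-level
#' sets) the owning-group ID columns. Numbers are written in shortest
#' round-trip form so re-parsing reproduces the exact values.
#'
#' @param points A `point_set` from [run_query()] or [drill_down()].
#' @param path Optional file path; when given the text is also written there.
#' @return The CSV text (single string), invisibly when `path` is given.
#' @export
export_csv <- function(points, path = NULL) {
  stopifnot(inherits(points, "point_set"))
  state <- attr(points, "state")
  id_names <- attr(points, "id_names")
  gcols <- attr(points, "group_id_cols")
  cols <- character()
  body <- list()
  for (nm in id_names) {
    cols <- c(cols, nm)
    body[[nm]] <- csv_field(points[[nm]])
  }
  xname <- if (is.null(state)) "x" else state$x_feature
  cols <- c(cols, xname)
  body[[xname]] <- num_repr(points$x)
  if ("y" %in% names(points)) {
    yname <- if (is.null(state) || is.null(state$y_feature)) "y" else state$y_feature
    cols <- c(cols, yname)
    body[[yname]] <- num_repr(points$y)
  }
  for (g in gcols) {
    cols <- c(cols, g)
    body[[g]] <- csv_field(points[[g]])
  }
  lines <- c(paste(csv_field(cols), collapse = ","),
             if (nrow(points)) do.call(paste, c(body, list(sep = ","))))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(text, con, sep = "", useBytes = TRUE)
    return(invisible(text))
  }
  text
}

## ---- SVG export -----------------------------------------------------------

svg_canvas <- function(width, height) {
  doc <- xml2::xml_new_root(
    "svg", xmlns = "http://www.w3.org/2000/svg",
    width = as.character(width), height = as.character(height),
    viewBox = sprintf("0 0 %d %d", width, height)
  )
  doc
}

linear_scale <- function(domain, range) {
  span <- domain[2] - domain[1]
  if (span == 0) span <- 1   # degenerate domain: centre the points
  force(domain); force(range)
  function(v) range[1] + (v - domain[1]) / span * (range[2] - range[1])
}

svg_axes <- function(doc, width, height, margin, xlab, ylab) {
  xml2::xml_add_child(doc, "line", class = "axis",
                      x1 = as.character(margin), y1 = as.character(height - margin),
                      x2 = as.character(width - margin), y2 = as.character(height - margin),
                      stroke = "black")
  xml2::xml_add_child(doc, "line", class = "axis",
                      x1 = as.character(margin), y1 = as.character(margin),
                      x2 = as.character(margin), y2 = as.character(height - margin),
                      stroke = "black")
  xl <- xml2::xml_add_child(doc, "text", class = "axis-label x-label",
                            x = as.character(width / 2),
                            y = as.character(height - margin / 4),
                            `text-anchor` = "middle")
  xml2::xml_text(xl) <- xlab
  yl <- xml2::xml_add_child(doc, "text", class = "axis-label y-label",
                            x = as.character(margin / 4),
                            y = as.character(height / 2),
                            transform = sprintf("rotate(-90 %s %s)", margin / 4, height / 2),
                            `text-anchor` = "middle")
  xml2::xml_text(yl) <- ylab
  invisible(doc)
}

#' Export a result as an SVG document
#'
#' Renders a scatter plot (point sets), bar chart (histograms) or density
#' trace (KDE curves) as standalone SVG 1.1 text. Every data point carries
#' `class="point"`, every histogram bar `class="bar"` and the density trace
#' `class="density"`, so exported plots remain machine-queryable.
#'
#' @param x A `point_set`, `histogram_result` or `density_curve`.
#' @param path Optional output file path.
#' @param width,height Canvas size in pixels.
#' @param ... Unused.
#' @return SVG text (single string); invisibly when `path` is given.
#' @export
export_svg <- function(x, path = NULL, width = 640, height = 480, ...) {
  UseMethod("export_svg")
}

finish_svg <- function(doc, path) {
  text <- as.character(doc)
  if (!is.null(path)) {
    writeLines(text, path, useBytes = TRUE)
    return(invisible(text))
  }
  text
}

#' @export
export_svg.point_set <- function(x, path = NULL, width = 640, height = 480, ...) {
  if (nrow(x) == 0) {
    sm_abort("sm_export_error", "cannot render an empty point set")
  }
  state <- attr(x, "state")
  margin <- 50
  has_y <- "y" %in% names(x)
  ys <- if (has_y) x$y else rep(0, nrow(x))
  sx <- linear_scale(range(x$x), c(margin, width - margin))
  sy <- linear_scale(range(ys), c(height - margin, margin))
  doc <- svg_canvas(width, height)
  svg_axes(doc, width, height, margin,
           xlab = if (is.null(state)) "x" else state$x_feature,
           ylab = if (!has_y) "" else if (is.null(state$y_feature)) "y" else state$y_feature)
  for (i in seq_len(nrow(x))) {
    xml2::xml_add_child(doc, "circle", class = "point",
                        cx = num_repr(sx(x$x[i])), cy = num_repr(sy(ys[i])),
                        r = "3", fill = "steelblue", `fill-opacity` = "0.7")
  }
  finish_svg(doc, path)
}

#' @export
export_svg.histogram_result <- function(x, path = NULL, width = 640, height = 480, ...) {
  counts <- x$counts
  if (length(counts) == 0 || all(vapply(counts, length, integer(1)) == 0)) {
    sm_abort("sm_export_error", "cannot render an empty histogram")
  }
  margin <- 50
  k <- length(x$bin_edges) - 1
  n_series <- length(counts)
  max_count <- max(unlist(counts), 1)
  sx <- linear_scale(range(x$bin_edges), c(margin, width - margin))
  sy <- linear_scale(c(0, max_count), c(height - margin, margin))
  doc <- svg_canvas(width, height)
  svg_axes(doc, width, height, margin, xlab = "value", ylab = "count")
  fills <- rep(c("steelblue", "tomato", "seagreen", "goldenrod", "orchid"),
               length.out = n_series)
  for (s in seq_len(n_series)) {
    for (b in seq_len(k)) {
      x0 <- sx(x$bin_edges[b])
      x1 <- sx(x$bin_edges[b + 1])
      bw <- (x1 - x0) / n_series
      top <- sy(counts[[s]][b])
      xml2::xml_add_child(
        doc, "rect", class = "bar",
        `data-series` = names(counts)[s],
        x = num_repr(x0 + (s - 1) * bw), y = num_repr(top),
        width = num_repr(max(bw, 0)),
        height = num_repr(max((height - margin) - top, 0)),
        fill = fills[s], `fill-opacity` = "0.7", stroke = "white"
      )
    }
  }
  finish_svg(doc, path)
}

#' @export
export_svg.density_curve <- function(x, path = NULL, width = 640, height = 480, ...) {
  if (length(x$grid) == 0) {
    sm_abort("sm_export_error", "cannot render an empty density curve")
  }
  margin <- 50
  sx <- linear_scale(range(x$grid), c(margin, width - margin))
  sy <- linear_scale(c(0, max(x$density)), c(height - margin, margin))
  doc <- svg_canvas(width, height)
  svg_axes(doc, width, height, margin, xlab = "value", ylab = "density")
  d <- paste0("M", paste(num_repr(sx(x$grid)), num_repr(sy(x$density)),
                         sep = ",", collapse = " L"))
  xml2::xml_add_child(doc, "path", class = "density", d = d,
                      fill = "none", stroke = "steelblue", `stroke-width` = "1.5")
  finish_svg(doc, path)
}

#' @export
export_svg.default <- function(x, ...) {
  sm_abort("sm_export_error",
           sprintf("no SVG renderer for class %s", class(x)[1]))
}

## ---- Share tokens ---------------------------------------------------------

SHARE_VERSION <- 1L

#' Encode a query state as a URL-safe share token
#'
#' The complete query state (level, axes, aggregation, filters, transforms,
#' selection) is serialized to canonical JSON, deflate-compressed and
#' base64url-encoded with a version prefix. Tokens are self-contained: no
#' server-side state is needed to replay the query.
#'
#' @param state A [query_state()].
#' @return Token string of the form `v1.<base64url>`; safe to place in a
#'   query-string parameter without percent-encoding.
#' @export
encode_share <- function(state) {
  json <- state_to_json(state)
  payload <- memCompress(charToRaw(json), type = "gzip")
  b64 <- gsub("[\r\n]", "", jsonlite::base64url_enc(payload))
  paste0("v", SHARE_VERSION, ".", b64)
}

#' Decode a share token back into a query state
#'
#' @param token Token produced by [encode_share()]. A tampered token or a
#'   token from a newer format version fails with `sm_share_token_error`;
#'   decoding never silently degrades.
#' @return A [query_state()] whose canonical JSON is byte-identical to the
#'   encoded state's.
#' @export
decode_share <- function(token) {
  stopifnot(is.character(token), length(token) == 1)
  m <- regmatches(token, regexec("^v([0-9]+)\\.(.+)$", token))[[1]]
  if (length(m) != 3) {
    sm_abort("sm_share_token_error", "malformed share token (missing version prefix)")
  }
  version <- as.integer(m[2])
  if (version != SHARE_VERSION) {
    sm_abort("sm_share_token_error",
             sprintf("share token version %d is not supported (this build reads v%d)",
                     version, SHARE_VERSION))
  }
  json <- tryCatch({
    raw <- jsonlite::base64url_dec(m[3])
    rawToChar(memDecompress(raw, type = "gzip"))
  }, error = function(e) {
    sm_abort("sm_share_token_error",
             sprintf("cannot decode share token: %s", conditionMessage(e)))
  })
  tryCatch(state_from_json(json), error = function(e) {
    sm_abort("sm_share_token_error",
             sprintf("share token does not contain a valid query state: %s",
                     conditionMessage(e)))
  })
}
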