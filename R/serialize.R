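# JSON-lines persistence for property graphs: one record per kind, node and
# edge. Numbers are written in shortest round-trip decimal form so a
# serialize -> deserialize cycle reproduces numeric properties exactly.

#' Write a property graph to a JSON-lines instance file
#'
#' One UTF-8 JSON object per line: kind records
#' (`{"record":"kind",...}`), node records (`{"record":"node","kind":...,
#' "ids":...,"properties":...,"labels":[...]}`) and edge records referencing
#' nodes by kind + ID values. Output ordering is stable (kinds in
#' registration order, nodes sorted by ID values, edges sorted by key), so
#' equal graphs serialize to byte-identical files.
#'
#' @param graph A [property_graph()].
#' @param path Output file path (conventionally `*.jsonl`).
#' @return `path`, invisibly.
#' @seealso [read_graph()]
#' @export
write_graph <- function(graph, path) {
  lines <- character()
  for (ki in graph$kinds) {
    lines <- c(lines, canonical_json(list(
      record = "kind", name = ki$name, role = ki$role,
      self_descriptive = ki$self_descriptive,
      label_catalog = as.list(sort(graph$labels[[ki$name]], method = "radix"))
    )))
  }
  for (kind in names(graph$kinds)) {
    tab_keys <- sort(ls(graph$index[[kind]], all.names = TRUE), method = "radix")
    for (key in tab_keys) {
      node <- graph$nodes[[graph$index[[kind]][[key]]]]
      props <- node$properties
      lines <- c(lines, canonical_json(list(
        record = "node", kind = kind,
        ids = as.list(node$id_values),
        properties = if (length(props)) props else stats::setNames(list(), character()),
        labels = as.list(sort(node$labels, method = "radix"))
      )))
    }
  }
  ekeys <- sort(ls(graph$edges, all.names = TRUE), method = "radix")
  for (ek in ekeys) {
    e <- graph$edges[[ek]]
    s <- graph$nodes[[e$source]]
    t <- graph$nodes[[e$target]]
    lines <- c(lines, canonical_json(list(
      record = "edge", relation = e$relation,
      source = list(kind = s$kind, ids = as.list(s$id_values)),
      target = list(kind = t$kind, ids = as.list(t$id_values))
    )))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a property graph from a JSON-lines instance file
#'
#' @param path File written by [write_graph()].
#' @return A [property_graph()].
#' @export
read_graph <- function(path) {
  if (!file.exists(path)) {
    sm_abort("sm_io_error", sprintf("instance file '%s' does not exist", path))
  }
  lines <- readLines(path, encoding = "UTF-8")
  graph <- property_graph()
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    rec <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    if (identical(rec$record, "kind")) {
      register_kind(graph, rec$name, role = rec$role,
                    self_descriptive = isTRUE(rec$self_descriptive))
      if (length(rec$label_catalog)) {
        graph$labels[[rec$name]] <- unlist(rec$label_catalog)
      }
    } else if (identical(rec$record, "node")) {
      props <- lapply(rec$properties, function(v) if (is.null(v)) NA_real_ else v)
      nid <- add_node(graph, rec$kind,
                      id_values = unlist(rec$ids),
                      properties = props)
      labs <- unlist(rec$labels)
      if (length(labs)) {
        set_labels(graph, rec$kind, unlist(rec$ids),
                   stats::setNames(rep(1, length(labs)), labs))
      }
    } else if (identical(rec$record, "edge")) {
      sid <- node_id_of(graph, rec$source$kind, unlist(rec$source$ids))
      tid <- node_id_of(graph, rec$target$kind, unlist(rec$target$ids))
      if (is.null(sid) || is.null(tid)) {
        sm_abort("sm_format_error", "edge record references an unknown node")
      }
      connect(graph, sid, tid, rec$relation)
    } else {
      sm_abort("sm_format_error",
               sprintf("unknown record type '%s' in instance file", rec$record))
    }
  }
  graph
}
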