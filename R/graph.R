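# Property-graph store for screen data.
#
# The screen data model is a property graph: objects of interest (genes,
# cells, images, ...) are nodes carrying tuples of typed properties and sets
# of categorical labels; edges record how objects relate (a cell belongs to a
# gene's population, was segmented out of an image). One node kind per graph
# is the *grouping* object — the top-level entity of the screen — and one is
# the *descriptive* object carrying the per-object quantitative features.
#
# The store is an environment-backed S3 object with O(1) node lookup by
# external identity (kind + ordered ID property values) and adjacency lists
# for traversal. Mutation invalidates cached tabular views.

new_graph_env <- function() {
  g <- new.env(parent = emptyenv())
  g$kinds <- list()            # name -> list(name, role, self_descriptive)
  g$nodes <- new.env(parent = emptyenv())   # node_id -> node record
  g$index <- list()            # kind -> env(id_key -> node_id)
  g$adj <- new.env(parent = emptyenv())     # node_id -> character vec of neighbour node_ids
  g$edges <- new.env(parent = emptyenv())   # "src|rel|tgt" -> list(source, target, relation)
  g$features <- list()         # kind -> character vec of NUMBER property names
  g$labels <- list()           # kind -> character vec of registered label names
  g$counter <- 0L
  g$cache <- new.env(parent = emptyenv())
  class(g) <- "property_graph"
  g
}

#' Create an empty property graph
#'
#' Constructs the in-memory graph store that holds an imported screen:
#' typed nodes (grouping, descriptive and metadata objects) with property
#' tuples and label sets, connected by named edges.
#'
#' @return A `property_graph` object (environment-backed; modified in place
#'   by [add_node()], [connect()] and [set_labels()]).
#' @seealso [register_kind()], [import_screen()]
#' @export
property_graph <- function() new_graph_env()

invalidate_cache <- function(graph) {
  rm(list = ls(graph$cache, all.names = TRUE), envir = graph$cache)
  invisible(graph)
}

#' Register an object kind
#'
#' Declares a node type before nodes of that type are added. Exactly one
#' kind per graph may have the grouping role; a single-layer screen is
#' modelled as a grouping kind with `self_descriptive = TRUE`.
#'
#' @param graph A [property_graph()].
#' @param name Kind name, e.g. `"Gene"`, `"Cell"`, `"Image"`.
#' @param role One of `"grouping"`, `"descriptive"`, `"metadata"`.
#' @param self_descriptive Logical; the grouping kind also carries the
#'   feature data (single data layer).
#' @return The graph, invisibly.
#' @export
register_kind <- function(graph, name,
                          role = c("grouping", "descriptive", "metadata"),
                          self_descriptive = FALSE) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!is.null(graph$kinds[[name]])) {
    sm_abort("sm_schema_error", sprintf("kind '%s' is already registered", name))
  }
  if (role == "grouping" && length(grouping_kind(graph, required = FALSE))) {
    sm_abort("sm_schema_error", "a graph can have only one grouping kind")
  }
  graph$kinds[[name]] <- list(name = name, role = role,
                              self_descriptive = isTRUE(self_descriptive))
  graph$index[[name]] <- new.env(parent = emptyenv())
  graph$features[[name]] <- character()
  graph$labels[[name]] <- character()
  invisible(graph)
}

kind_info <- function(graph, kind) {
  ki <- graph$kinds[[kind]]
  if (is.null(ki)) {
    sm_abort("sm_schema_error", sprintf("unknown kind '%s'", kind))
  }
  ki
}

grouping_kind <- function(graph, required = TRUE) {
  for (ki in graph$kinds) if (ki$role == "grouping") return(ki$name)
  if (required) sm_abort("sm_schema_error", "graph has no grouping kind")
  character()
}

descriptive_kind <- function(graph) {
  for (ki in graph$kinds) {
    if (ki$role == "descriptive") return(ki$name)
  }
  for (ki in graph$kinds) {
    if (ki$role == "grouping" && ki$self_descriptive) return(ki$name)
  }
  sm_abort("sm_schema_error", "graph has no descriptive kind")
}

#' List registered kinds
#' @param graph A [property_graph()].
#' @return A tibble with columns `name`, `role`, `self_descriptive`.
#' @export
graph_kinds <- function(graph) {
  tibble(
    name = unname(vapply(graph$kinds, `[[`, character(1), "name")),
    role = unname(vapply(graph$kinds, `[[`, character(1), "role")),
    self_descriptive = unname(vapply(graph$kinds, `[[`, logical(1),
                                     "self_descriptive"))
  )
}

#' Add a node
#'
#' Inserts a node identified by its ordered ID property values. Numeric
#' properties must be finite or `NA` (explicitly missing; a missing value is
#' excluded from queries, never coerced to 0). The kind's feature catalog is
#' extended with any new numeric property names.
#'
#' @param graph A [property_graph()].
#' @param kind Registered kind name.
#' @param id_values Named character vector of ID property values; non-empty
#'   for grouping and descriptive kinds.
#' @param properties Named list of property values (numeric for NUMBER,
#'   character for TEXT/URL).
#' @param on_duplicate `"error"` raises on an existing (kind, id) pair;
#'   `"merge"` adds new properties to the existing node and raises
#'   only when an already-set property would change value.
#' @return The internal node id (string), invisibly usable with [connect()].
#' @export
add_node <- function(graph, kind, id_values, properties = list(),
                     on_duplicate = c("error", "merge")) {
  on_duplicate <- match.arg(on_duplicate)
  ki <- kind_info(graph, kind)
  id_values <- as.character(id_values) |> stats::setNames(names(id_values))
  if (ki$role != "metadata" && (length(id_values) == 0 || is.null(names(id_values)))) {
    sm_abort("sm_schema_error",
             sprintf("nodes of kind '%s' require named id values", kind))
  }
  key <- id_key(id_values)
  idx <- graph$index[[kind]]
  existing <- idx[[key]]
  if (!is.null(existing)) {
    if (on_duplicate == "error") {
      sm_abort("sm_duplicate_object_error",
               sprintf("a %s node with ids (%s) already exists",
                       kind, paste(id_values, collapse = ", ")))
    }
    node <- graph$nodes[[existing]]
    for (p in names(properties)) {
      v <- properties[[p]]
      old <- node$properties[[p]]
      if (is.null(old) || (length(old) == 1 && is.na(old))) {
        node$properties[[p]] <- v           # new or previously missing: fill
      } else if (length(v) == 1 && is.na(v)) {
        # incoming missing never erases a known value
      } else if (!identical(unname(old), unname(v)) &&
                 !(is.numeric(old) && is.numeric(v) && old == v)) {
        sm_abort("sm_import_conflict_error",
                 sprintf("conflicting value for property '%s' on %s (%s)",
                         p, kind, paste(id_values, collapse = ", ")))
      }
    }
    graph$nodes[[existing]] <- node
    register_features(graph, kind, properties)
    invalidate_cache(graph)
    return(invisible(existing))
  }
  check_properties(properties)
  graph$counter <- graph$counter + 1L
  node_id <- paste0("n", graph$counter)
  graph$nodes[[node_id]] <- list(
    node_id = node_id, kind = kind, id_values = id_values,
    properties = properties, labels = character()
  )
  idx[[key]] <- node_id
  register_features(graph, kind, properties)
  invalidate_cache(graph)
  invisible(node_id)
}

check_properties <- function(properties) {
  for (p in names(properties)) {
    v <- properties[[p]]
    if (is.numeric(v) && length(v) == 1 && !is.na(v) && !is.finite(v)) {
      sm_abort("sm_schema_error",
               sprintf("numeric property '%s' must be finite or missing", p))
    }
  }
}

register_features <- function(graph, kind, properties) {
  num <- names(properties)[vapply(properties, is.numeric, logical(1))]
  new <- setdiff(num, graph$features[[kind]])
  if (length(new)) graph$features[[kind]] <- c(graph$features[[kind]], new)
  invisible(graph)
}

#' Look up a node id by external identity
#' @inheritParams add_node
#' @return The internal node id, or `NULL` when absent.
#' @export
node_id_of <- function(graph, kind, id_values) {
  kind_info(graph, kind)
  graph$index[[kind]][[id_key(id_values)]]
}

get_node <- function(graph, node_id) {
  node <- graph$nodes[[node_id]]
  if (is.null(node)) {
    sm_abort("sm_missing_node_error", sprintf("no node with id '%s'", node_id))
  }
  node
}

#' Number of nodes of a kind
#' @inheritParams register_kind
#' @export
node_count <- function(graph, kind) {
  kind_info(graph, kind)
  length(ls(graph$index[[kind]], all.names = TRUE))
}

#' Connect two nodes
#'
#' Adds an undirectedly-traversable, named edge. Edges have set semantics:
#' connecting the same (source, target, relation) twice leaves one edge.
#'
#' @param graph A [property_graph()].
#' @param source_id,target_id Internal node ids (from [add_node()] or
#'   [node_id_of()]).
#' @param relation Edge relation name, e.g. `"MEMBER_OF"`.
#' @return The edge record (list with source, target, relation), invisibly.
#' @export
connect <- function(graph, source_id, target_id, relation) {
  get_node(graph, source_id)
  get_node(graph, target_id)
  ekey <- paste(source_id, relation, target_id, sep = "|")
  edge <- list(source = source_id, target = target_id, relation = relation)
  if (is.null(graph$edges[[ekey]])) {
    graph$edges[[ekey]] <- edge
    graph$adj[[source_id]] <- unique(c(graph$adj[[source_id]], target_id))
    graph$adj[[target_id]] <- unique(c(graph$adj[[target_id]], source_id))
    invalidate_cache(graph)
  }
  invisible(edge)
}

#' Number of (logical) edges in the graph
#' @param graph A [property_graph()].
#' @export
edge_count <- function(graph) length(ls(graph$edges, all.names = TRUE))

#' Neighbours of a node
#' @param graph A [property_graph()].
#' @param node_id Internal node id.
#' @return Character vector of neighbouring node ids.
#' @export
neighbors_of <- function(graph, node_id) {
  get_node(graph, node_id)
  nb <- graph$adj[[node_id]]
  if (is.null(nb)) character() else nb
}

#' Grouping node that owns a descriptive node
#'
#' Every descriptive object belongs to exactly one grouping object, possibly
#' through intermediate metadata nodes (cell -> image -> gene). Found by
#' breadth-first traversal; zero or more than one reachable grouping node is
#' a graph-integrity failure.
#'
#' @param graph A [property_graph()].
#' @param node_id Internal node id of a descriptive node.
#' @return The internal node id of the owning grouping node.
#' @export
owning_group <- function(graph, node_id) {
  node <- get_node(graph, node_id)
  gk <- grouping_kind(graph)
  ki <- kind_info(graph, node$kind)
  if (ki$role == "grouping" && ki$self_descriptive) return(node_id)
  if (ki$role != "descriptive") {
    sm_abort("sm_graph_integrity_error",
             sprintf("node '%s' is not a descriptive node", node_id))
  }
  seen <- new.env(parent = emptyenv())
  seen[[node_id]] <- TRUE
  frontier <- node_id
  found <- character()
  while (length(frontier)) {
    nxt <- character()
    for (cur in frontier) {
      for (nb in neighbors_of(graph, cur)) {
        if (!is.null(seen[[nb]])) next
        seen[[nb]] <- TRUE
        if (graph$nodes[[nb]]$kind == gk) {
          found <- c(found, nb)
        } else {
          nxt <- c(nxt, nb)
        }
      }
    }
    frontier <- nxt
  }
  found <- unique(found)
  if (length(found) != 1) {
    sm_abort("sm_graph_integrity_error",
             sprintf("descriptive node '%s' reaches %d grouping nodes (expected exactly 1)",
                     node_id, length(found)))
  }
  found
}

#' Assign binary labels to a node
#'
#' Labels are categorical annotations on grouping objects, imported from a
#' 0/1 matrix: value 1 attaches the label, value 0 ensures it is absent.
#' Any other value is rejected.
#'
#' @param graph A [property_graph()].
#' @param kind Kind name.
#' @param id_values Named character vector identifying the node.
#' @param assignments Named vector/list of 0/1 values, names are label names.
#' @return The updated node record, invisibly.
#' @export
set_labels <- function(graph, kind, id_values, assignments) {
  node_id <- node_id_of(graph, kind, id_values)
  if (is.null(node_id)) {
    sm_abort("sm_missing_node_error",
             sprintf("no %s node with ids (%s)", kind,
                     paste(id_values, collapse = ", ")))
  }
  vals <- unlist(assignments)
  if (is.null(names(vals)) || !all(nzchar(names(vals)))) {
    sm_abort("sm_label_value_error", "label assignments must be named")
  }
  num <- suppressWarnings(as.numeric(vals))
  if (any(is.na(num)) || !all(num %in% c(0, 1))) {
    bad <- names(vals)[is.na(num) | !(num %in% c(0, 1))][1]
    sm_abort("sm_label_value_error",
             sprintf("label '%s' has non-binary value '%s' (must be 0 or 1)",
                     bad, vals[[bad]]))
  }
  node <- graph$nodes[[node_id]]
  on <- names(vals)[num == 1]
  off <- names(vals)[num == 0]
  node$labels <- union(setdiff(node$labels, off), on)
  graph$nodes[[node_id]] <- node
  graph$labels[[kind]] <- union(graph$labels[[kind]], names(vals))
  invalidate_cache(graph)
  invisible(node)
}

#' Tabular view of all nodes of a kind
#'
#' Materializes one kind's nodes as a tibble: internal `.node_id`, the ID
#' columns, every property column (numeric for NUMBER, character otherwise)
#' and a `.labels` list-column. Cached until the graph is mutated; this is
#' the view the query engine operates on.
#'
#' @inheritParams register_kind
#' @return A tibble with one row per node.
#' @export
node_table <- function(graph, kind) {
  kind_info(graph, kind)
  cached <- graph$cache[[paste0("tab:", kind)]]
  if (!is.null(cached)) return(cached)
  keys <- ls(graph$index[[kind]], all.names = TRUE)
  ids <- vapply(keys, function(k) graph$index[[kind]][[k]], character(1),
                USE.NAMES = FALSE)
  nodes <- lapply(ids, function(i) graph$nodes[[i]])
  if (length(nodes) == 0) {
    out <- tibble(.node_id = character(), .labels = list())
  } else {
    id_names <- names(nodes[[1]]$id_values)
    id_cols <- lapply(id_names, function(nm)
      vapply(nodes, function(n) unname(n$id_values[[nm]]), character(1)))
    names(id_cols) <- id_names
    prop_names <- unique(unlist(lapply(nodes, function(n) names(n$properties))))
    prop_cols <- lapply(prop_names, function(p) {
      vals <- lapply(nodes, function(n) {
        v <- n$properties[[p]]
        if (is.null(v)) NA else v
      })
      if (p %in% graph$features[[kind]]) {
        vapply(vals, function(v) if (is.character(v)) NA_real_ else as.numeric(v), numeric(1))
      } else {
        vapply(vals, function(v) if (is.na(v[1])) NA_character_ else as.character(v), character(1))
      }
    })
    names(prop_cols) <- prop_names
    out <- as_tibble(c(
      list(.node_id = vapply(nodes, `[[`, character(1), "node_id")),
      id_cols, prop_cols,
      list(.labels = lapply(nodes, `[[`, "labels"))
    ))
    out <- out[order(do.call(paste, c(unname(out[id_names]), list(sep = KEY_SEP))),
                     method = "radix"), ]
  }
  graph$cache[[paste0("tab:", kind)]] <- out
  out
}

# descriptive node id -> owning grouping node id, as a named character
# vector; cached.
ownership_map <- function(graph) {
  cached <- graph$cache[["ownership"]]
  if (!is.null(cached)) return(cached)
  dk <- descriptive_kind(graph)
  dt <- node_table(graph, dk)
  own <- vapply(dt$.node_id, function(i) owning_group(graph, i), character(1))
  names(own) <- dt$.node_id
  graph$cache[["ownership"]] <- own
  own
}

#' @export
print.property_graph <- function(x, ...) {
  kinds <- graph_kinds(x)
  cat("<property_graph>\n")
  for (i in seq_len(nrow(kinds))) {
    k <- kinds$name[i]
    cat(sprintf("  %s (%s): %d nodes, %d features, %d labels\n",
                k, kinds$role[i], node_count(x, k),
                length(x$features[[k]]), length(x$labels[[k]])))
  }
  cat(sprintf("  edges: %d\n", edge_count(x)))
  invisible(x)
}
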