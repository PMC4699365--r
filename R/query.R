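# Multi-level query engine.
#
# A query is a complete, serializable state: the level it runs at (grouping
# or descriptive), the features on the axes, how descriptive values roll up
# to grouping objects, conjunctive filters at either level, axis transforms
# and an optional rectangular area selection. Evaluation order is fixed:
# descriptive-level filters first, then aggregation (grouping level only),
# then grouping-level filters, then transforms, then the selection.

AGGREGATIONS <- c("mean", "median", "count", "min", "max")

#' Describe a query
#'
#' @param level `"grouping"` (one point per grouping object, descriptive
#'   features rolled up with `aggregation`) or `"descriptive"` (one point
#'   per descriptive object).
#' @param x_feature,y_feature Feature names; `y_feature = NULL` gives a
#'   distribution (single-axis) query.
#' @param aggregation How descriptive values roll up at grouping level:
#'   `"mean"`, `"median"`, `"count"`, `"min"` or `"max"`. Ignored at
#'   descriptive level.
#' @param filters List of [label_filter()] / [range_filter()] clauses,
#'   combined conjunctively.
#' @param x_transform,y_transform `"linear"` or `"log10"`; log10 requires
#'   all transformed values to be positive at evaluation time.
#' @param selection Optional closed axis-aligned rectangle, as a list with
#'   `x_min`, `x_max`, `y_min`, `y_max` (y bounds ignored for single-axis
#'   queries).
#' @return A `query_state` object.
#' @export
query_state <- function(level = c("grouping", "descriptive"),
                        x_feature, y_feature = NULL,
                        aggregation = "mean", filters = list(),
                        x_transform = c("linear", "log10"),
                        y_transform = c("linear", "log10"),
                        selection = NULL) {
  level <- match.arg(level)
  x_transform <- match.arg(x_transform)
  y_transform <- match.arg(y_transform)
  if (!aggregation %in% AGGREGATIONS) {
    sm_abort("sm_query_error",
             sprintf("unknown aggregation '%s' (expected %s)", aggregation,
                     paste(AGGREGATIONS, collapse = ", ")))
  }
  stopifnot(is.character(x_feature), length(x_feature) == 1)
  if (!is.null(selection)) {
    need <- c("x_min", "x_max", "y_min", "y_max")
    selection <- stats::setNames(lapply(need, function(f) {
      v <- selection[[f]]
      if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v)
    }), need)
  }
  structure(list(
    level = level, x_feature = x_feature, y_feature = y_feature,
    aggregation = aggregation, filters = filters,
    x_transform = x_transform, y_transform = y_transform,
    selection = selection
  ), class = "query_state")
}

#' Label-presence / label-absence filter clause
#'
#' @param kind Object kind the clause targets (grouping or descriptive).
#' @param label Label name.
#' @param present `TRUE` keeps entities carrying the label, `FALSE` keeps
#'   those not carrying it.
#' @return A `filter_clause`.
#' @export
label_filter <- function(kind, label, present = TRUE) {
  structure(list(type = if (present) "label_present" else "label_absent",
                 kind = kind, label = label),
            class = "filter_clause")
}

#' Numeric-range filter clause
#'
#' Keeps entities whose property value lies in the closed interval
#' `[low, high]`. When the clause targets the grouping kind and the property
#' is a descriptive feature, the value tested is that feature aggregated
#' with the query's aggregation method.
#'
#' @inheritParams label_filter
#' @param property NUMBER property name.
#' @param low,high Interval bounds (use `-Inf`/`Inf` for one-sided).
#' @return A `filter_clause`.
#' @export
range_filter <- function(kind, property, low = -Inf, high = Inf) {
  structure(list(type = "numeric_range", kind = kind, property = property,
                 low = as.numeric(low), high = as.numeric(high)),
            class = "filter_clause")
}

#' @export
print.query_state <- function(x, ...) {
  cat(sprintf("<query_state> level=%s x=%s%s agg=%s filters=%d\n",
              x$level, x$x_feature,
              if (is.null(x$y_feature)) "" else paste0(" y=", x$y_feature),
              x$aggregation, length(x$filters)))
  invisible(x)
}

#' Features and labels available for a kind
#'
#' @param graph A [property_graph()].
#' @param kind Registered kind name.
#' @return A list with sorted unique `features` (NUMBER property names) and
#'   `labels`.
#' @export
list_catalog <- function(graph, kind) {
  if (is.null(graph$kinds[[kind]])) {
    sm_abort("sm_query_error", sprintf("unknown kind '%s'", kind))
  }
  list(features = sort(unique(graph$features[[kind]]), method = "radix"),
       labels = sort(unique(graph$labels[[kind]]), method = "radix"))
}

# descriptive table with owning-group id columns prefixed "group."
descriptive_table <- function(graph) {
  cached <- graph$cache[["desc_joined"]]
  if (!is.null(cached)) return(cached)
  dk <- descriptive_kind(graph)
  gk <- grouping_kind(graph)
  dt <- node_table(graph, dk)
  if (identical(dk, gk)) {
    out <- dt
    out$.group_id <- dt$.node_id
  } else {
    own <- ownership_map(graph)
    out <- dt
    out$.group_id <- unname(own[dt$.node_id])
  }
  gt <- node_table(graph, gk)
  gid_names <- group_id_names(graph)
  gids <- gt[match(out$.group_id, gt$.node_id), gid_names, drop = FALSE]
  names(gids) <- paste0("group.", gid_names)
  out <- dplyr::bind_cols(out, gids)
  graph$cache[["desc_joined"]] <- out
  out
}

group_id_names <- function(graph) {
  gk <- grouping_kind(graph)
  gt <- node_table(graph, gk)
  if (nrow(gt) == 0) return(character())
  names(graph$nodes[[gt$.node_id[1]]]$id_values)
}

entity_id_names <- function(graph, kind) {
  tab <- node_table(graph, kind)
  if (nrow(tab) == 0) return(character())
  names(graph$nodes[[tab$.node_id[1]]]$id_values)
}

check_feature <- function(graph, feature, level) {
  dk <- descriptive_kind(graph)
  gk <- grouping_kind(graph)
  known <- if (level == "descriptive") graph$features[[dk]] else {
    union(graph$features[[dk]], graph$features[[gk]])
  }
  if (!feature %in% known) {
    sm_abort("sm_query_error", sprintf("unknown feature '%s'", feature))
  }
}

aggregate_one <- function(values, method) {
  values <- values[!is.na(values)]
  if (length(values) == 0) return(NA_real_)
  switch(method,
         mean = mean(values),
         median = median(values),   # ties: average of middle two
         count = as.numeric(length(values)),
         min = min(values),
         max = max(values))
}

#' Roll a descriptive feature up to grouping objects
#'
#' One value per grouping object that has at least one descriptive member
#' with a non-missing value of the feature; missing values are excluded from
#' the aggregate (and from `count`).
#'
#' @param graph A [property_graph()].
#' @param feature Descriptive NUMBER property name.
#' @param method `"mean"`, `"median"`, `"count"`, `"min"` or `"max"`.
#' @return A tibble: grouping ID columns plus `value`, sorted by IDs.
#' @export
aggregate_feature <- function(graph, feature, method = "mean") {
  dk <- descriptive_kind(graph)
  if (!feature %in% graph$features[[dk]]) {
    sm_abort("sm_query_error",
             sprintf("unknown descriptive feature '%s'", feature))
  }
  if (!method %in% AGGREGATIONS) {
    sm_abort("sm_query_error", sprintf("unknown aggregation '%s'", method))
  }
  dt <- descriptive_table(graph)
  gid <- paste0("group.", group_id_names(graph))
  out <- dt |>
    dplyr::filter(!is.na(.data[[feature]])) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(gid))) |>
    dplyr::summarise(value = aggregate_one(.data[[feature]], method),
                     .groups = "drop")
  names(out)[seq_along(gid)] <- sub("^group\\.", "", gid)
  dplyr::arrange(out, dplyr::across(-dplyr::all_of("value")))
}

# Evaluate one clause against the descriptive table -> logical mask
eval_descriptive_clause <- function(graph, clause, tab) {
  dk <- descriptive_kind(graph)
  if (clause$type == "numeric_range") {
    if (!clause$property %in% graph$features[[dk]]) {
      sm_abort("sm_query_error",
               sprintf("unknown feature '%s' for kind '%s'", clause$property, dk))
    }
    v <- tab[[clause$property]]
    !is.na(v) & v >= clause$low & v <= clause$high
  } else {
    if (!clause$label %in% graph$labels[[dk]]) {
      sm_abort("sm_query_error",
               sprintf("unknown label '%s' for kind '%s'", clause$label, dk))
    }
    has <- vapply(tab$.labels, function(l) clause$label %in% l, logical(1))
    if (clause$type == "label_present") has else !has
  }
}

# Evaluate one grouping-kind clause -> set of allowed grouping .node_ids.
# `dt` is the descriptive table *after* descriptive-level filtering, so that
# aggregates seen by grouping clauses reflect the sequential filter order.
eval_grouping_clause <- function(graph, clause, aggregation, dt) {
  gk <- grouping_kind(graph)
  gt <- node_table(graph, gk)
  if (clause$type == "numeric_range") {
    if (clause$property %in% graph$features[[gk]]) {
      v <- gt[[clause$property]]
      keep <- !is.na(v) & v >= clause$low & v <= clause$high
      return(gt$.node_id[keep])
    }
    dk <- descriptive_kind(graph)
    if (!clause$property %in% graph$features[[dk]]) {
      sm_abort("sm_query_error",
               sprintf("unknown feature '%s' for kind '%s'", clause$property, gk))
    }
    agg <- dt |>
      dplyr::filter(!is.na(.data[[clause$property]])) |>
      dplyr::group_by(.data$.group_id) |>
      dplyr::summarise(value = aggregate_one(.data[[clause$property]], aggregation),
                       .groups = "drop")
    agg$.group_id[!is.na(agg$value) & agg$value >= clause$low & agg$value <= clause$high]
  } else {
    if (!clause$label %in% graph$labels[[gk]]) {
      sm_abort("sm_query_error",
               sprintf("unknown label '%s' for kind '%s'", clause$label, gk))
    }
    has <- vapply(gt$.labels, function(l) clause$label %in% l, logical(1))
    gt$.node_id[if (clause$type == "label_present") has else !has]
  }
}

apply_transform <- function(values, transform, axis, ids) {
  if (transform == "linear") return(values)
  bad <- which(values <= 0)
  if (length(bad)) {
    sm_abort("sm_transform_error",
             sprintf("log10 %s-axis requires positive values; offending entities: %s",
                     axis, paste(head(ids[bad], 5), collapse = ", ")),
             entities = ids[bad])
  }
  log10(values)
}

new_point_set <- function(tab, level, state, n_dropped, id_names, group_id_cols = character()) {
  attr(tab, "level") <- level
  attr(tab, "state") <- state
  attr(tab, "n_dropped") <- n_dropped
  attr(tab, "id_names") <- id_names
  attr(tab, "group_id_cols") <- group_id_cols
  class(tab) <- c("point_set", class(tibble()))
  tab
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> level=%s records=%d dropped=%d\n",
              attr(x, "level"), nrow(x), attr(x, "n_dropped")))
  NextMethod()
}

#' Run a query
#'
#' Evaluates a [query_state()] against a graph and returns the plot-ready
#' point set. Records with a missing value on a requested axis are dropped
#' (pairwise complete) and counted in the result's `n_dropped` attribute.
#' Records are sorted by entity ID values for deterministic output.
#'
#' @param graph A [property_graph()].
#' @param state A [query_state()].
#' @return A `point_set` tibble: entity ID columns, `x`, optionally `y`,
#'   and (at descriptive level) `group.*` owner ID columns.
#' @export
run_query <- function(graph, state) {
  stopifnot(inherits(state, "query_state"))
  check_feature(graph, state$x_feature, state$level)
  if (!is.null(state$y_feature)) check_feature(graph, state$y_feature, state$level)
  dk <- descriptive_kind(graph)
  gk <- grouping_kind(graph)
  desc_clauses <- Filter(function(cl) identical(cl$kind, dk) && !identical(dk, gk),
                         state$filters)
  group_clauses <- Filter(function(cl) identical(cl$kind, gk), state$filters)
  other <- Filter(function(cl) !identical(cl$kind, dk) && !identical(cl$kind, gk),
                  state$filters)
  if (length(other)) {
    sm_abort("sm_query_error",
             sprintf("filter targets unknown kind '%s'", other[[1]]$kind))
  }

  dt <- descriptive_table(graph)
  keep <- rep(TRUE, nrow(dt))
  for (cl in desc_clauses) keep <- keep & eval_descriptive_clause(graph, cl, dt)
  dt <- dt[keep, , drop = FALSE]

  gid_names <- group_id_names(graph)
  if (state$level == "descriptive") {
    allowed_groups <- NULL
    for (cl in group_clauses) {
      ag <- eval_grouping_clause(graph, cl, state$aggregation, dt)
      allowed_groups <- if (is.null(allowed_groups)) ag else intersect(allowed_groups, ag)
    }
    if (!is.null(allowed_groups)) dt <- dt[dt$.group_id %in% allowed_groups, , drop = FALSE]
    id_names <- entity_id_names(graph, dk)
    gcols <- paste0("group.", gid_names)
    out <- dt[, c(id_names, gcols), drop = FALSE]
    out$x <- dt[[state$x_feature]]
    if (!is.null(state$y_feature)) out$y <- dt[[state$y_feature]]
  } else {
    gt <- node_table(graph, gk)
    gfeat <- graph$features[[gk]]
    agg_axis <- function(feature) {
      if (feature %in% gfeat && !identical(dk, gk)) {
        stats::setNames(gt[[feature]], gt$.node_id)
      } else {
        agg <- dt |>
          dplyr::filter(!is.na(.data[[feature]])) |>
          dplyr::group_by(.data$.group_id) |>
          dplyr::summarise(value = aggregate_one(.data[[feature]], state$aggregation),
                           .groups = "drop")
        stats::setNames(agg$value, agg$.group_id)[gt$.node_id]
      }
    }
    xs <- agg_axis(state$x_feature)
    out <- gt[, gid_names, drop = FALSE]
    out$x <- unname(xs)
    if (!is.null(state$y_feature)) out$y <- unname(agg_axis(state$y_feature))
    allowed <- gt$.node_id
    for (cl in group_clauses) {
      allowed <- intersect(allowed,
                           eval_grouping_clause(graph, cl, state$aggregation, dt))
    }
    sel <- gt$.node_id %in% allowed
    out <- out[sel, , drop = FALSE]
    id_names <- gid_names
    gcols <- character()
  }

  n0 <- nrow(out)
  complete <- !is.na(out$x)
  if (!is.null(state$y_feature)) complete <- complete & !is.na(out$y)
  out <- out[complete, , drop = FALSE]
  n_dropped <- n0 - nrow(out)

  ids_text <- do.call(paste, c(unname(out[id_names]), list(sep = "/")))
  out$x <- apply_transform(out$x, state$x_transform, "x", ids_text)
  if (!is.null(state$y_feature)) {
    out$y <- apply_transform(out$y, state$y_transform, "y", ids_text)
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
  out <- out[order(do.call(paste, c(unname(out[id_names]), list(sep = KEY_SEP))),
                   method = "radix"), , drop = FALSE]
  new_point_set(as_tibble(out), state$level, state, n_dropped, id_names, gcols)
}

#' Drill down from grouping objects to their descriptive members
#'
#' Expands a grouping-level selection (e.g. genes picked in a scatter plot)
#' into the descriptive-level records that compose it, tagged with the
#' owning group's IDs for downstream colouring.
#'
#' @param graph A [property_graph()].
#' @param grouping_ids Grouping IDs: a character vector (single-ID-column
#'   graphs), a data frame of ID columns, or a list of named vectors.
#' @param feature_x,feature_y Descriptive features for the axes
#'   (`feature_y` optional).
#' @return A descriptive-level `point_set`; empty input gives an empty set.
#' @export
drill_down <- function(graph, grouping_ids, feature_x, feature_y = NULL) {
  dk <- descriptive_kind(graph)
  gk <- grouping_kind(graph)
  check_feature(graph, feature_x, "descriptive")
  if (!is.null(feature_y)) check_feature(graph, feature_y, "descriptive")
  gid_names <- group_id_names(graph)
  keys <- normalize_group_keys(graph, grouping_ids, gid_names)
  for (k in seq_along(keys$node)) {
    if (is.na(keys$node[k])) {
      sm_abort("sm_missing_node_error",
               sprintf("unknown %s ids (%s)", gk, keys$text[k]))
    }
  }
  dt <- descriptive_table(graph)
  dt <- dt[dt$.group_id %in% keys$node, , drop = FALSE]
  id_names <- entity_id_names(graph, dk)
  gcols <- paste0("group.", gid_names)
  out <- dt[, c(id_names, gcols), drop = FALSE]
  out$x <- dt[[feature_x]]
  if (!is.null(feature_y)) out$y <- dt[[feature_y]]
  n0 <- nrow(out)
  complete <- !is.na(out$x)
  if (!is.null(feature_y)) complete <- complete & !is.na(out$y)
  out <- out[complete, , drop = FALSE]
  out <- out[order(do.call(paste, c(unname(out[id_names]), list(sep = KEY_SEP))),
                   method = "radix"), , drop = FALSE]
  state <- query_state(level = "descriptive", x_feature = feature_x,
                       y_feature = feature_y)
  new_point_set(as_tibble(out), "descriptive", state, n0 - nrow(out),
                id_names, gcols)
}

normalize_group_keys <- function(graph, grouping_ids, gid_names) {
  gk <- grouping_kind(graph)
  if (is.data.frame(grouping_ids)) {
    rows <- lapply(seq_len(nrow(grouping_ids)), function(i) {
      stats::setNames(as.character(unlist(grouping_ids[i, gid_names])), gid_names)
    })
  } else if (is.list(grouping_ids)) {
    rows <- lapply(grouping_ids, function(v) {
      if (is.null(names(v))) stats::setNames(as.character(v), gid_names) else v
    })
  } else {
    if (length(gid_names) != 1 && length(grouping_ids) > 0) {
      sm_abort("sm_query_error",
               sprintf("%s has %d ID columns; pass a data frame of ids",
                       gk, length(gid_names)))
    }
    rows <- lapply(as.character(grouping_ids), function(v) {
      stats::setNames(v, gid_names)
    })
  }
  node <- vapply(rows, function(idv) {
    nid <- node_id_of(graph, gk, idv)
    if (is.null(nid)) NA_character_ else nid
  }, character(1))
  list(node = node,
       text = vapply(rows, paste, character(1), collapse = ","))
}
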