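# Importer for the typed three-header-row screen CSV dialect and the
# companion binary label matrix.
#
# Screen file layout (RFC 4180 CSV, UTF-8, decimal point, no thousands
# separators):
#   row 1 - column headers (become property names)
#   row 2 - object names (which object of interest owns each column)
#   row 3 - property types: TEXT, NUMBER, ID or URL (case-insensitive)
#   row 4+ - one descriptive-object instance per row
#
# Label file layout: one header row; the leading columns matching the
# grouping object's ID property names identify the grouping object, every
# remaining column is a binary (0/1) label.

PROPERTY_TYPES <- c("TEXT", "NUMBER", "ID", "URL")

#' Parse a property-type token
#'
#' Tokens are matched case-insensitively and stored canonical upper-case.
#' Only `TEXT`, `NUMBER`, `ID` and `URL` exist; `NUMBER` is the only type
#' queryable as a feature.
#'
#' @param token Character scalar.
#' @return One of `"TEXT"`, `"NUMBER"`, `"ID"`, `"URL"`.
#' @export
parse_property_type <- function(token) {
  up <- toupper(trimws(token))
  if (!up %in% PROPERTY_TYPES) {
    sm_abort("sm_format_error",
             sprintf("unknown property type '%s' (expected TEXT, NUMBER, ID or URL)",
                     token))
  }
  up
}

read_csv_rows <- function(path) {
  if (!file.exists(path)) {
    sm_abort("sm_io_error", sprintf("file '%s' does not exist", path))
  }
  counts <- count.fields(path, sep = ",", quote = "\"", blank.lines.skip = FALSE)
  # drop trailing blank lines (count.fields reports NA inside quotes, never here)
  while (length(counts) && (is.na(counts[length(counts)]) || counts[length(counts)] == 0)) {
    counts <- counts[-length(counts)]
  }
  if (length(counts) == 0) {
    return(list(rows = matrix(character(), 0, 0), field_counts = integer()))
  }
  ncol <- counts[1]
  ragged <- which(counts != ncol)
  df <- read.csv(path, header = FALSE, colClasses = "character",
                 check.names = FALSE, stringsAsFactors = FALSE,
                 blank.lines.skip = FALSE, fill = TRUE,
                 col.names = paste0("V", seq_len(max(counts, na.rm = TRUE))),
                 encoding = "UTF-8")
  rows <- as.matrix(df)
  dimnames(rows) <- NULL
  list(rows = rows, field_counts = counts, ragged = ragged)
}

#' Parse the three header rows of a screen file
#'
#' Builds the schema: per column the property name, the owning object and
#' the property type; plus which object plays the grouping and which the
#' descriptive role. When roles are not supplied, the object owning the
#' first ID column is taken as grouping and the object owning the most
#' NUMBER columns as descriptive. Every object must own at least one ID
#' column, otherwise its rows could not be merged into nodes.
#'
#' @param header_rows A list (or matrix) of exactly 3 character rows of equal
#'   length: headers, object names, property types.
#' @param grouping,descriptive Object names for the two roles; `NULL` invokes
#'   the default heuristic.
#' @return A `schema_descriptor`: tibble of columns plus role attributes.
#' @export
parse_schema <- function(header_rows, grouping = NULL, descriptive = NULL) {
  if (is.matrix(header_rows)) {
    header_rows <- lapply(seq_len(nrow(header_rows)), function(i) header_rows[i, ])
  }
  if (length(header_rows) != 3) {
    sm_abort("sm_format_error",
             sprintf("expected 3 header rows (headers, object names, property types), got %d",
                     length(header_rows)))
  }
  lens <- lengths(header_rows)
  if (length(unique(lens)) != 1) {
    sm_abort("sm_format_error",
             sprintf("header rows have unequal column counts: %s",
                     paste(lens, collapse = ", ")))
  }
  headers <- unname(trimws(header_rows[[1]]))
  objects <- unname(trimws(header_rows[[2]]))
  if (any(!nzchar(headers))) {
    sm_abort("sm_format_error", "empty column header")
  }
  if (any(!nzchar(objects))) {
    sm_abort("sm_format_error", "empty object name in row 2")
  }
  ptypes <- character(length(headers))
  for (j in seq_along(headers)) {
    tok <- header_rows[[3]][j]
    ok <- toupper(trimws(tok)) %in% PROPERTY_TYPES
    if (!ok) {
      sm_abort("sm_format_error",
               sprintf("unknown property type '%s' in column %d ('%s')",
                       tok, j, headers[j]))
    }
    ptypes[j] <- toupper(trimws(tok))
  }
  cols <- tibble(
    header = headers, object = objects, ptype = ptypes,
    column_index = seq_along(headers) - 1L
  )
  for (obj in unique(objects)) {
    if (!any(ptypes == "ID" & objects == obj)) {
      sm_abort("sm_format_error",
               sprintf("object '%s' has no ID column; its rows cannot be merged into nodes",
                       obj))
    }
  }
  if (is.null(grouping)) {
    grouping <- objects[which(ptypes == "ID")[1]]
  }
  if (is.null(descriptive)) {
    n_num <- vapply(unique(objects), function(o) sum(ptypes == "NUMBER" & objects == o),
                    integer(1))
    descriptive <- if (all(n_num == 0)) grouping else names(n_num)[which.max(n_num)]
  }
  for (role_obj in c(grouping, descriptive)) {
    if (!role_obj %in% objects) {
      sm_abort("sm_format_error",
               sprintf("object '%s' does not appear in the schema's object row", role_obj))
    }
  }
  structure(cols,
            class = c("schema_descriptor", class(cols)),
            grouping = grouping, descriptive = descriptive)
}

#' @export
print.schema_descriptor <- function(x, ...) {
  cat(sprintf("<schema_descriptor> grouping=%s descriptive=%s\n",
              attr(x, "grouping"), attr(x, "descriptive")))
  NextMethod()
}

schema_objects <- function(schema) unique(schema$object)

#' Build a property graph from screen data rows
#'
#' Each data row is one descriptive-object instance. For every object named
#' in the schema, one node is created per distinct ID tuple; rows referring
#' to an existing (object, ID tuple) merge into that node, and a merged row
#' that would change an already-known property value is a conflict. Each
#' descriptive row is linked to the co-occurring grouping node (relation
#' `MEMBER_OF`) and to each co-occurring metadata node (relation
#' `DERIVED_FROM`). NUMBER cells parse as decimal/scientific numbers; empty
#' NUMBER cells are stored as missing, never as 0.
#'
#' @param data_rows Character matrix (rows x schema columns) of data rows,
#'   or a list of character vectors.
#' @param schema A [parse_schema()] result.
#' @param first_data_row File row number of the first data row, used in
#'   error coordinates (4 when the file has the standard 3 header rows).
#' @return A [property_graph()].
#' @export
import_screen <- function(data_rows, schema, first_data_row = 4L) {
  if (is.list(data_rows) && !is.matrix(data_rows)) {
    lens <- lengths(data_rows)
    bad <- which(lens != nrow(schema))
    if (length(bad)) {
      sm_abort("sm_format_error",
               sprintf("row %d has %d fields, expected %d",
                       first_data_row + bad[1] - 1L, lens[bad[1]], nrow(schema)))
    }
    data_rows <- do.call(rbind, lapply(data_rows, as.character))
    if (is.null(data_rows)) data_rows <- matrix(character(), 0, nrow(schema))
  }
  if (ncol(data_rows) != nrow(schema) && nrow(data_rows) > 0) {
    sm_abort("sm_format_error",
             sprintf("data has %d columns, schema has %d", ncol(data_rows), nrow(schema)))
  }
  grouping <- attr(schema, "grouping")
  descriptive <- attr(schema, "descriptive")
  graph <- property_graph()
  register_kind(graph, grouping, role = "grouping",
                self_descriptive = identical(grouping, descriptive))
  for (obj in schema_objects(schema)) {
    if (obj == grouping) next
    register_kind(graph, obj,
                  role = if (obj == descriptive) "descriptive" else "metadata")
  }
  n <- nrow(data_rows)
  if (n == 0) return(graph)

  # parse NUMBER columns up front, with file coordinates on failure
  numeric_vals <- list()
  for (j in which(schema$ptype == "NUMBER")) {
    cells <- trimws(data_rows[, j])
    vals <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(vals) & nzchar(cells))
    if (length(bad)) {
      sm_abort("sm_import_error",
               sprintf("cannot parse '%s' as a number at row %d, column %d ('%s')",
                       cells[bad[1]], first_data_row + bad[1] - 1L, j,
                       schema$header[j]),
               row = first_data_row + bad[1] - 1L, column = j)
    }
    numeric_vals[[as.character(j)]] <- vals
  }

  obj_keys <- list()
  obj_node_ids <- list()
  for (obj in schema_objects(schema)) {
    idc <- which(schema$ptype == "ID" & schema$object == obj)
    propc <- which(schema$ptype != "ID" & schema$object == obj)
    keys <- do.call(paste, c(lapply(idc, function(j) data_rows[, j]),
                             list(sep = KEY_SEP)))
    obj_keys[[obj]] <- keys
    first_idx <- which(!duplicated(keys))
    # merge-conflict scan: a key must map to a single property tuple
    if (length(propc)) {
      prop_sig <- do.call(paste, c(lapply(propc, function(j) data_rows[, j]),
                                   list(sep = KEY_SEP)))
      tuples <- paste(keys, prop_sig, sep = PAIR_SEP)
      conflict_keys <- unique(keys[duplicated(keys) & !duplicated(tuples)])
      if (length(conflict_keys)) {
        bad_row <- which(keys == conflict_keys[1])[2]
        sm_abort("sm_import_conflict_error",
                 sprintf("row %d repeats %s ids with different property values",
                         first_data_row + bad_row - 1L, obj))
      }
    }
    node_ids <- character(length(first_idx))
    for (m in seq_along(first_idx)) {
      i <- first_idx[m]
      idv <- stats::setNames(as.character(data_rows[i, idc]), schema$header[idc])
      props <- list()
      for (j in propc) {
        p <- schema$header[j]
        props[[p]] <- if (schema$ptype[j] == "NUMBER") {
          numeric_vals[[as.character(j)]][i]
        } else {
          data_rows[i, j]
        }
      }
      node_ids[m] <- add_node(graph, obj, idv, props)
    }
    lookup <- stats::setNames(node_ids, keys[first_idx])
    obj_node_ids[[obj]] <- unname(lookup[keys])
  }

  desc_ids <- obj_node_ids[[descriptive]]
  for (obj in schema_objects(schema)) {
    if (obj == descriptive) next
    relation <- if (obj == grouping) "MEMBER_OF" else "DERIVED_FROM"
    pair_keys <- paste(desc_ids, obj_node_ids[[obj]])
    keep <- which(!duplicated(pair_keys))
    for (i in keep) {
      connect(graph, desc_ids[i], obj_node_ids[[obj]][i], relation)
    }
  }
  graph
}

#' Read and import a screen CSV file
#'
#' Convenience wrapper: reads the file, parses the three header rows and
#' imports the data rows.
#'
#' @param path Screen CSV file path.
#' @inheritParams parse_schema
#' @return A [property_graph()].
#' @export
read_screen <- function(path, grouping = NULL, descriptive = NULL) {
  parsed <- read_csv_rows(path)
  if (length(parsed$ragged)) {
    sm_abort("sm_format_error",
             sprintf("row %d has %d fields, expected %d",
                     parsed$ragged[1], parsed$field_counts[parsed$ragged[1]],
                     parsed$field_counts[1]))
  }
  if (nrow(parsed$rows) < 3) {
    sm_abort("sm_format_error",
             "file must have 3 header rows (headers, object names, property types)")
  }
  schema <- parse_schema(parsed$rows[1:3, , drop = FALSE],
                         grouping = grouping, descriptive = descriptive)
  data_rows <- parsed$rows[-(1:3), , drop = FALSE]
  import_screen(data_rows, schema)
}

#' Attach binary labels to grouping nodes
#'
#' Each label row is matched to a grouping node by its leading ID columns;
#' labels with value 1 are attached (1 = the grouping object possesses the
#' annotation, 0 = otherwise). Rows referencing unknown grouping IDs are
#' collected as warnings, not fatal errors: screens routinely annotate
#' objects absent from an imported subset.
#'
#' @param graph A populated [property_graph()].
#' @param label_rows Character matrix of label data rows (no header).
#' @param n_id_columns How many leading columns are grouping IDs.
#' @param label_names Names of the remaining columns, in order.
#' @return Number of grouping nodes that received at least one label, with
#'   attribute `"unknown"` listing unmatched ID tuples.
#' @export
import_labels <- function(graph, label_rows, n_id_columns, label_names) {
  stopifnot(n_id_columns >= 1)
  if (length(label_names) == 0 || anyDuplicated(label_names)) {
    sm_abort("sm_format_error", "label names must be non-empty and unique")
  }
  if (is.list(label_rows) && !is.matrix(label_rows)) {
    label_rows <- do.call(rbind, lapply(label_rows, as.character))
  }
  gk <- grouping_kind(graph)
  gt <- node_table(graph, gk)
  annotated <- character()
  unknown <- character()
  if (!is.null(label_rows) && nrow(label_rows) > 0) {
    if (ncol(label_rows) != n_id_columns + length(label_names)) {
      sm_abort("sm_format_error",
               sprintf("label rows have %d columns, expected %d ids + %d labels",
                       ncol(label_rows), n_id_columns, length(label_names)))
    }
    # grouping identity match is by the ordered ID *values*
    gkeys <- do.call(paste, c(unname(as.list(
      gt[, setdiff(names(gt), c(".node_id", ".labels"))[seq_len(n_id_columns)]]
    )), list(sep = KEY_SEP)))
    id_name_cols <- names(graph$nodes[[gt$.node_id[1]]]$id_values)
    for (i in seq_len(nrow(label_rows))) {
      key <- paste(label_rows[i, seq_len(n_id_columns)], collapse = KEY_SEP)
      hit <- match(key, gkeys)
      if (is.na(hit)) {
        unknown <- c(unknown, paste(label_rows[i, seq_len(n_id_columns)],
                                    collapse = ","))
        next
      }
      vals <- label_rows[i, n_id_columns + seq_along(label_names)]
      assignments <- stats::setNames(as.list(vals), label_names)
      num <- suppressWarnings(as.numeric(unlist(assignments)))
      if (any(is.na(num)) || !all(num %in% c(0, 1))) {
        bad <- which(is.na(num) | !(num %in% c(0, 1)))[1]
        sm_abort("sm_label_value_error",
                 sprintf("non-binary label value '%s' for label '%s' in label row %d",
                         vals[bad], label_names[bad], i))
      }
      idv <- stats::setNames(as.character(label_rows[i, seq_len(n_id_columns)]),
                             id_name_cols[seq_len(n_id_columns)])
      set_labels(graph, gk, idv, assignments)
      if (any(num == 1)) annotated <- c(annotated, key)
    }
  }
  graph$labels[[gk]] <- union(graph$labels[[gk]], label_names)
  if (length(unknown)) {
    warn(sprintf("%d label row(s) reference unknown %s ids: %s",
                 length(unknown), gk, paste(unknown, collapse = "; ")),
         class = "sm_unknown_group_warning")
  }
  structure(length(unique(annotated)), unknown = unknown)
}

#' Read and apply a label CSV file
#'
#' The file has one header row. Leading header names that match the grouping
#' object's ID property names are taken as the ID columns; all remaining
#' columns are labels.
#'
#' @param graph A populated [property_graph()].
#' @param path Label CSV path.
#' @return See [import_labels()].
#' @export
import_labels_file <- function(graph, path) {
  parsed <- read_csv_rows(path)
  if (nrow(parsed$rows) < 1) {
    sm_abort("sm_format_error", "label file has no header row")
  }
  header <- trimws(parsed$rows[1, ])
  gk <- grouping_kind(graph)
  gt <- node_table(graph, gk)
  if (nrow(gt) == 0) {
    sm_abort("sm_format_error", "graph has no grouping nodes to label")
  }
  id_names <- names(graph$nodes[[gt$.node_id[1]]]$id_values)
  n_id <- 0L
  while (n_id < length(header) && header[n_id + 1L] %in% id_names) {
    n_id <- n_id + 1L
  }
  if (n_id == 0) {
    sm_abort("sm_format_error",
             sprintf("no leading label-file column matches a %s ID property (%s)",
                     gk, paste(id_names, collapse = ", ")))
  }
  import_labels(graph, parsed$rows[-1, , drop = FALSE],
                n_id_columns = n_id,
                label_names = header[-seq_len(n_id)])
}

#' Validate a screen file without importing it
#'
#' Collects every problem that would make [read_screen()] fail, with file
#' coordinates (1-based row, 1-based column where applicable). An empty
#' report means the file imports cleanly.
#'
#' @inheritParams read_screen
#' @return A `validation_report` tibble with columns `row`, `column`, `issue`.
#' @export
validate_screen_file <- function(path, grouping = NULL, descriptive = NULL) {
  issues <- list()
  add_issue <- function(row, column, issue) {
    issues[[length(issues) + 1]] <<- tibble(row = as.integer(row),
                                            column = as.integer(column),
                                            issue = issue)
  }
  if (!file.exists(path)) {
    sm_abort("sm_io_error", sprintf("file '%s' does not exist", path))
  }
  parsed <- read_csv_rows(path)
  nr <- length(parsed$field_counts)
  if (nr < 3) {
    add_issue(nr + 1L, NA, "missing property-type row (need 3 header rows)")
    return(finish_report(issues))
  }
  for (r in parsed$ragged) {
    add_issue(r, NA, sprintf("row has %d fields, expected %d",
                             parsed$field_counts[r], parsed$field_counts[1]))
  }
  if (length(parsed$ragged)) return(finish_report(issues))
  schema <- tryCatch(
    parse_schema(parsed$rows[1:3, , drop = FALSE],
                 grouping = grouping, descriptive = descriptive),
    error = function(e) {
      add_issue(3L, NA, conditionMessage(e))
      NULL
    }
  )
  if (is.null(schema)) return(finish_report(issues))
  data_rows <- parsed$rows[-(1:3), , drop = FALSE]
  if (nrow(data_rows)) {
    for (j in which(schema$ptype == "NUMBER")) {
      cells <- trimws(data_rows[, j])
      vals <- suppressWarnings(as.numeric(cells))
      for (i in which(is.na(vals) & nzchar(cells))) {
        add_issue(i + 3L, j,
                  sprintf("cannot parse '%s' as a number in NUMBER column '%s'",
                          cells[i], schema$header[j]))
      }
    }
    if (length(issues) == 0) {
      tryCatch(import_screen(data_rows, schema),
               error = function(e) add_issue(NA, NA, conditionMessage(e)))
    }
  }
  finish_report(issues)
}

finish_report <- function(issues) {
  out <- if (length(issues)) dplyr::bind_rows(issues) else {
    tibble(row = integer(), column = integer(), issue = character())
  }
  class(out) <- c("validation_report", class(out))
  out
}
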