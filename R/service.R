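# Read-only JSON-over-HTTP query service.
#
# Routes (reconstructed; the JSON payloads are the plot-ready data a client
# renders from):
#   GET  /health                liveness + node counts
#   GET  /catalog/{kind}        features and labels of a kind
#   POST /query                 body: query-state JSON -> point set
#   POST /histogram             body: {state, axis?, bins?} -> histogram
#   POST /kde                   body: {state, axis?, bandwidth?} -> curve
#   POST /regression            body: {state} -> regression fit
#   POST /compare               body: {state_a, state_b} -> comparison
#   GET  /share/{token}         replay an encoded share token -> point set
#
# Errors: 400 malformed request body, 404 unknown route/kind, 422 a
# well-formed query referencing unknown features/labels or failing a
# transform. Every response body is {"status": ..., "payload"/"message": ...}.

point_set_payload <- function(ps) {
  id_names <- attr(ps, "id_names")
  gcols <- attr(ps, "group_id_cols")
  records <- lapply(seq_len(nrow(ps)), function(i) {
    rec <- list(ids = stats::setNames(
      lapply(id_names, function(nm) ps[[nm]][i]), id_names
    ), x = ps$x[i])
    if ("y" %in% names(ps)) rec$y <- ps$y[i]
    if (length(gcols)) {
      gv <- lapply(gcols, function(g) ps[[g]][i])
      rec$group <- stats::setNames(gv, sub("^group\\.", "", gcols))
    }
    rec
  })
  list(level = attr(ps, "level"),
       n_records = nrow(ps),
       n_dropped = attr(ps, "n_dropped"),
       state = state_to_payload(attr(ps, "state")),
       records = records)
}

histogram_payload <- function(h) {
  list(bin_edges = as.list(h$bin_edges),
       counts = lapply(h$counts, as.list),
       series_names = as.list(h$series_names))
}

density_payload <- function(d) {
  list(grid = as.list(d$grid), density = as.list(d$density),
       bandwidth = d$bandwidth, n = d$n)
}

regression_payload <- function(f) {
  list(slope = f$slope, intercept = f$intercept, r_squared = f$r_squared,
       slope_se = f$slope_se, intercept_se = f$intercept_se,
       n_points = f$n_points, degenerate = f$degenerate)
}

comparison_payload <- function(cp) {
  list(level = cp$level, x_feature = cp$x_feature, y_feature = cp$y_feature,
       shared_range = lapply(cp$shared_range, as.list),
       summary = lapply(seq_len(nrow(cp$summary)), function(i) as.list(cp$summary[i, ])),
       delta = lapply(seq_len(nrow(cp$delta)), function(i) as.list(cp$delta[i, ])))
}

api_response <- function(status_code, payload = NULL, message = NULL) {
  body <- if (is.null(message)) {
    list(status = "ok", payload = payload)
  } else {
    list(status = "error", message = message)
  }
  list(status = status_code,
       content_type = "application/json; charset=utf-8",
       body = canonical_json(body))
}

axis_values <- function(graph, body, default_axis = "x") {
  if (is.null(body$state)) {
    sm_abort("sm_query_error", "request body must carry a 'state' object")
  }
  state <- payload_to_state(body$state)
  ps <- run_query(graph, state)
  axis <- if (is.null(body$axis)) default_axis else body$axis
  if (!axis %in% c("x", "y") || is.null(ps[[axis]])) {
    sm_abort("sm_query_error", sprintf("axis '%s' is not present in the result", axis))
  }
  list(values = ps[[axis]], point_set = ps, state = state)
}

#' Handle one API request in-process
#'
#' The pure request handler behind [serve_screen()]: same routing, status
#' codes and JSON bodies, without a socket. Useful for programmatic access
#' and for testing transport transparency.
#'
#' @param graph A [property_graph()].
#' @param method `"GET"` or `"POST"`.
#' @param path Request path, e.g. `"/query"`.
#' @param body Request body text (JSON) for POST routes.
#' @return A list with `status` (HTTP code), `content_type` and `body`
#'   (JSON text).
#' @export
handle_request <- function(graph, method, path, body = NULL) {
  parse_body <- function() {
    if (is.null(body) || !nzchar(body)) {
      sm_abort("sm_bad_request", "empty request body")
    }
    tryCatch(jsonlite::fromJSON(body, simplifyVector = FALSE),
             error = function(e) {
               sm_abort("sm_bad_request",
                        sprintf("malformed JSON body: %s", conditionMessage(e)))
             })
  }
  handler <- function() {
    segs <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]
    route <- if (length(segs)) segs[1] else ""
    if (method == "GET" && route == "health") {
      kinds <- graph_kinds(graph)
      counts <- stats::setNames(
        lapply(kinds$name, function(k) node_count(graph, k)), kinds$name)
      return(api_response(200L, list(service = "screenminer",
                                     nodes = counts,
                                     edges = edge_count(graph))))
    }
    if (method == "GET" && route == "catalog" && length(segs) == 2) {
      cat <- list_catalog(graph, segs[2])
      return(api_response(200L, list(kind = segs[2],
                                     features = as.list(cat$features),
                                     labels = as.list(cat$labels))))
    }
    if (method == "POST" && route == "query") {
      state <- payload_to_state(parse_body())
      return(api_response(200L, point_set_payload(run_query(graph, state))))
    }
    if (method == "POST" && route == "histogram") {
      b <- parse_body()
      av <- axis_values(graph, b)
      h <- histogram(av$values,
                     bins = b$bins,
                     name = if (is.null(b$axis)) "x" else b$axis)
      return(api_response(200L, histogram_payload(h)))
    }
    if (method == "POST" && route == "kde") {
      b <- parse_body()
      av <- axis_values(graph, b)
      d <- kde(av$values, bandwidth = b$bandwidth)
      return(api_response(200L, density_payload(d)))
    }
    if (method == "POST" && route == "regression") {
      b <- parse_body()
      av <- axis_values(graph, b)
      return(api_response(200L, regression_payload(fit_regression(av$point_set))))
    }
    if (method == "POST" && route == "compare") {
      b <- parse_body()
      if (is.null(b$state_a) || is.null(b$state_b)) {
        sm_abort("sm_bad_request", "compare needs 'state_a' and 'state_b'")
      }
      a <- run_query(graph, payload_to_state(b$state_a))
      bb <- run_query(graph, payload_to_state(b$state_b))
      return(api_response(200L, comparison_payload(compare_plots(a, bb))))
    }
    if (method == "GET" && route == "share" && length(segs) == 2) {
      state <- decode_share(segs[2])
      return(api_response(200L, point_set_payload(run_query(graph, state))))
    }
    api_response(404L, message = sprintf("no route %s %s", method, path))
  }
  tryCatch(
    handler(),
    sm_bad_request = function(e) api_response(400L, message = conditionMessage(e)),
    sm_share_token_error = function(e) api_response(400L, message = conditionMessage(e)),
    sm_query_error = function(e) api_response(422L, message = conditionMessage(e)),
    sm_transform_error = function(e) api_response(422L, message = conditionMessage(e)),
    sm_analytics_error = function(e) api_response(422L, message = conditionMessage(e)),
    screenminer_error = function(e) api_response(500L, message = conditionMessage(e)),
    error = function(e) api_response(500L, message = conditionMessage(e))
  )
}

#' httpuv application wrapping a graph
#'
#' @param graph A [property_graph()].
#' @return An app object suitable for `httpuv::startServer()`.
#' @export
screen_app <- function(graph) {
  list(call = function(req) {
    body <- tryCatch({
      if (!is.null(req$rook.input)) rawToChar(req$rook.input$read()) else NULL
    }, error = function(e) NULL)
    res <- handle_request(graph, req$REQUEST_METHOD, req$PATH_INFO, body)
    list(status = res$status,
         headers = list("Content-Type" = res$content_type),
         body = res$body)
  })
}

#' Serve a screen instance over HTTP
#'
#' Loads a JSON-lines instance file (or takes a live graph) and serves the
#' read-only JSON API. Blocks until interrupted; no endpoint mutates the
#' instance.
#'
#' @param instance Path to a [write_graph()] file, or a [property_graph()].
#' @param host Bind address.
#' @param port TCP port.
#' @param quiet Suppress the startup message.
#' @return Never returns under normal operation (runs the server loop).
#' @export
serve_screen <- function(instance, host = "127.0.0.1", port = 8080,
                         quiet = FALSE) {
  graph <- if (inherits(instance, "property_graph")) instance else read_graph(instance)
  if (!quiet) {
    message(sprintf("serving screen instance on http://%s:%d (read-only)", host, port))
  }
  httpuv::runServer(host, port, screen_app(graph))
}
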