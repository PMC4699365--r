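# Canonical JSON form of a query state: the single serialization shared by
# share tokens, the HTTP service and saved analyses. Stable key order and
# round-trip number formatting make equal states byte-identical.

state_to_payload <- function(state) {
  stopifnot(inherits(state, "query_state"))
  list(
    level = state$level,
    x_feature = state$x_feature,
    y_feature = state$y_feature,
    aggregation = state$aggregation,
    filters = lapply(state$filters, function(cl) {
      out <- list(type = cl$type, kind = cl$kind)
      if (cl$type == "numeric_range") {
        out$property <- cl$property
        # open bounds (infinite) are omitted; canonical JSON has no Inf
        if (is.finite(cl$low)) out$low <- cl$low
        if (is.finite(cl$high)) out$high <- cl$high
      } else {
        out$label <- cl$label
      }
      out
    }),
    x_transform = state$x_transform,
    y_transform = state$y_transform,
    selection = state$selection
  )
}

payload_to_state <- function(payload) {
  filters <- lapply(payload$filters, function(cl) {
    if (is.null(cl$type) || is.null(cl$kind)) {
      sm_abort("sm_query_error", "filter clause missing 'type' or 'kind'")
    }
    if (cl$type == "numeric_range") {
      range_filter(cl$kind, cl$property,
                   low = if (is.null(cl$low)) -Inf else cl$low,
                   high = if (is.null(cl$high)) Inf else cl$high)
    } else if (cl$type %in% c("label_present", "label_absent")) {
      label_filter(cl$kind, cl$label, present = cl$type == "label_present")
    } else {
      sm_abort("sm_query_error", sprintf("unknown filter type '%s'", cl$type))
    }
  })
  query_state(
    level = payload$level,
    x_feature = payload$x_feature,
    y_feature = payload$y_feature,
    aggregation = if (is.null(payload$aggregation)) "mean" else payload$aggregation,
    filters = filters,
    x_transform = if (is.null(payload$x_transform)) "linear" else payload$x_transform,
    y_transform = if (is.null(payload$y_transform)) "linear" else payload$y_transform,
    selection = payload$selection
  )
}

#' Serialize a query state to canonical JSON
#'
#' @param state A [query_state()].
#' @return A single JSON string; equal states produce byte-identical text.
#' @export
state_to_json <- function(state) {
  canonical_json(state_to_payload(state))
}

#' Parse a query state from JSON
#'
#' @param json JSON text produced by [state_to_json()] (or hand-written with
#'   the same fields).
#' @return A [query_state()].
#' @export
state_from_json <- function(json) {
  payload <- tryCatch(jsonlite::fromJSON(json, simplifyVector = FALSE),
                      error = function(e) {
                        sm_abort("sm_query_error",
                                 sprintf("invalid query-state JSON: %s",
                                         conditionMessage(e)))
                      })
  payload_to_state(payload)
}
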