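# Shared low-level helpers: condition classes, round-trip number formatting,
# canonical JSON. All package errors carry a subclass of "screenminer_error"
# so callers can branch on the failure kind rather than on message text.

sm_abort <- function(class, message, ...) {
  abort(message, class = c(class, "screenminer_error"), ...)
}

# Separators used to build flat string keys from ordered (name, value) pairs.
# \x1f/\x1e are unit/record separators: never legal in CSV field content we
# accept, so keys cannot collide.
KEY_SEP <- "\x1f"
PAIR_SEP <- "\x1e"

id_key <- function(id_values) {
  paste(names(id_values), id_values, sep = KEY_SEP, collapse = PAIR_SEP)
}

#' Round-trip decimal representation of numbers
#'
#' Formats doubles as decimal text that parses back to the exact binary
#' value, using the fewest of 15, 16 or 17 significant digits that round
#' trips (the `%g` format already trims trailing zeros, so most values come
#' out short). Used wherever numbers become text that must survive a round
#' trip: CSV export, graph serialization and canonical JSON.
#'
#' @param x Numeric vector. `NA` is rendered as `"NA"`.
#' @return Character vector, one representation per element.
#' @export
#' @examples
#' num_repr(c(0.1 + 0.2, 1/3, 7))
num_repr <- function(x) {
  x <- as.numeric(x)
  out <- character(length(x))
  na <- is.na(x)
  out[na] <- "NA"
  if (any(!is.finite(x[!na]))) {
    sm_abort("sm_export_error", "cannot represent non-finite number as decimal text")
  }
  todo <- which(!na)
  for (d in c(15L, 16L, 17L)) {
    if (!length(todo)) break
    s <- formatC(x[todo], digits = d, format = "g", width = -1L)
    ok <- as.numeric(s) == x[todo]
    out[todo[ok]] <- s[ok]
    todo <- todo[!ok]
  }
  if (length(todo)) out[todo] <- formatC(x[todo], digits = 17L, format = "g", width = -1L)
  out
}

json_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  # remaining C0 control characters, rare in practice
  if (any(grepl("[\x01-\x1f]", s))) {
    for (code in 1:31) {
      ch <- rawToChar(as.raw(code))
      if (ch %in% c("\n", "\r", "\t")) next
      s <- gsub(ch, sprintf("\\u%04x", code), s, fixed = TRUE)
    }
  }
  paste0("\"", s, "\"")
}

#' Canonical JSON serialization
#'
#' Deterministic JSON: object keys byte-sorted, no insignificant whitespace,
#' doubles in shortest round-trip form. Two structurally equal R values always
#' produce byte-identical text, which is what share tokens and replayable
#' query states require. Conventions: named lists become objects, unnamed
#' lists and atomic vectors of length != 1 become arrays, length-1 atomics
#' become scalars (wrap in `list()` to force an array), `NULL` and `NA`
#' become `null`.
#'
#' @param x An R value built from lists, character, numeric and logical.
#' @return A single JSON string.
#' @export
canonical_json <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && length(x) > 0 && all(nzchar(nm))) {
      o <- order(nm, method = "radix")
      inner <- vapply(
        o,
        function(i) paste0(json_escape(nm[i]), ":", canonical_json(x[[i]])),
        character(1)
      )
      return(paste0("{", paste0(inner, collapse = ","), "}"))
    }
    inner <- vapply(x, canonical_json, character(1))
    return(paste0("[", paste0(inner, collapse = ","), "]"))
  }
  if (length(x) != 1) {
    inner <- vapply(seq_along(x), function(i) canonical_json(x[[i]]), character(1))
    return(paste0("[", paste0(inner, collapse = ","), "]"))
  }
  if (is.character(x)) return(json_escape(x))
  if (is.logical(x)) {
    if (is.na(x)) return("null")
    return(if (x) "true" else "false")
  }
  if (is.numeric(x)) {
    if (is.na(x)) return("null")
    if (is.integer(x)) return(as.character(x))
    return(num_repr(x))
  }
  sm_abort("sm_export_error", sprintf("cannot serialize value of class %s", class(x)[1]))
}
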