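`%||%` <- function(x, y) if (is.null(x)) y else x

#' Canonical JSON serialization
#'
#' Serializes an R list to the canonical JSON text used throughout the
#' package: scalars unboxed, full numeric precision, `NULL` as JSON null.
#' Canonical here means: deterministic output for a given structure, so
#' rendered documents and tool payloads are diffable.
#'
#' @param x A list (or scalar) to serialize.
#' @return A single JSON string.
#' @export
canonical_json <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"))
}

#' Parse JSON without simplification
#'
#' Inverse of [canonical_json()]: objects stay named lists, arrays stay
#' unnamed lists, so structure round-trips exactly.
#'
#' @param txt JSON text.
#' @return The parsed structure.
#' @export
parse_json <- function(txt) {
  jsonlite::fromJSON(txt, simplifyVector = FALSE)
}

# classed condition constructors -----------------------------------------

bc_error <- function(class, message, ..., call = NULL) {
  structure(
    class = c(class, "biocrumbs_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
}

stop_validation <- function(paths, message = NULL) {
  msg <- message %||% paste0(
    "breadcrumb document invalid; violated field paths: ",
    paste(paths, collapse = ", ")
  )
  stop(bc_error("bc_validation_error", msg, paths = paths))
}

stop_serialization <- function(message) {
  stop(bc_error("bc_serialization_error", message))
}

stop_unsupported_method <- function(method) {
  stop(bc_error(
    "bc_unsupported_method_error",
    sprintf("unsupported HTTP method '%s' (allowed: GET, POST, PUT, DELETE)", method),
    method = method
  ))
}

stop_timeout <- function(message) {
  stop(bc_error("bc_timeout_error", message))
}

stop_upstream <- function(message, status = NULL) {
  stop(bc_error("eutils_upstream_error", message, status = status))
}

stop_parse <- function(message) {
  stop(bc_error("eutils_parse_error", message))
}

stop_config <- function(message) {
  stop(bc_error("eutils_config_error", message))
}

stop_path <- function(message, candidate = NULL) {
  stop(bc_error("bc_path_error", message, candidate = candidate))
}

stop_soft_format <- function(message, line) {
  stop(bc_error(
    "soft_format_error",
    sprintf("SOFT format error at line %d: %s", line, message),
    line = line
  ))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_nonempty_string <- function(x) is_string(x) && nzchar(x)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == trunc(x)
}

is_absolute_url <- function(x) {
  is_nonempty_string(x) && grepl("^[A-Za-z][A-Za-z0-9+.-]*://[^/[:space:]]+", x)
}

is_root_relative_url <- function(x) {
  is_nonempty_string(x) && grepl("^/", x) && !grepl("^//", x)
}

# Percent-encode a query parameter value.
url_encode <- function(x) curl::curl_escape(as.character(x))

build_query <- function(params) {
  if (length(params) == 0L) return("")
  stopifnot(!is.null(names(params)), all(nzchar(names(params))))
  paste(
    vapply(
      names(params),
      function(k) paste0(url_encode(k), "=", url_encode(params[[k]])),
      character(1)
    ),
    collapse = "&"
  )
}

append_query <- function(url, params) {
  q <- build_query(params)
  if (!nzchar(q)) return(url)
  sep <- if (grepl("\\?", url)) "&" else "?"
  paste0(url, sep, q)
}

monotonic_now <- function() {
  as.numeric(proc.time()[["elapsed"]])
}
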