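#' @title The breadcrumb metadata format
#'
#' @description
#' A *breadcrumb* is a small JSON document embedded in an HTML comment on a
#' service's web pages. It advertises the service's identity, whether a
#' native Model Context Protocol (MCP) endpoint exists (and where), and a
#' fallback API specification (endpoints with HTTP method, a semantic
#' concept tag, and parameter schemas) that an autonomous agent can use when
#' no native MCP endpoint is available.
#'
#' The normative comment grammar used by this package: an HTML comment whose
#' first non-whitespace token is the sentinel `mcp-breadcrumb`, followed by a
#' single JSON object, e.g.
#'
#' ```
#' <!-- mcp-breadcrumb
#' {"service": {"name": "demo", "version": "1.0.0"}, ...}
#' -->
#' ```
#'
#' @name breadcrumbs
NULL

BC_SENTINEL <- "mcp-breadcrumb"
BC_METHODS <- c("GET", "POST", "PUT", "DELETE")
BC_VALUE_TYPES <- c("string", "integer", "number", "boolean", "array")

#' Construct a parameter specification
#'
#' @param name Identifier (letters, digits, underscore; must not start with
#'   a digit). Unique within its endpoint.
#' @param value_type One of `"string"`, `"integer"`, `"number"`,
#'   `"boolean"`, `"array"`.
#' @param required Logical flag.
#' @param description Optional human-readable description.
#' @return A named list representing the parameter.
#' @export
param_spec <- function(name, value_type, required = FALSE, description = NULL) {
  p <- list(name = name, value_type = value_type, required = required)
  if (!is.null(description)) p$description <- description
  p
}

#' Construct an endpoint specification
#'
#' @param method HTTP verb: one of GET, POST, PUT, DELETE.
#' @param url Absolute (`https://...`) or root-relative (`/api/...`) URL
#'   template.
#' @param concept Non-empty semantic concept tag (e.g. `"search_data"`,
#'   `"download_file"`). Plain strings; ontology identifiers can be attached
#'   via `concept_iris`.
#' @param params List of [param_spec()] entries.
#' @param concept_iris Optional character vector of ontology identifiers.
#' @param example Optional example usage URL.
#' @return A named list representing the endpoint.
#' @export
endpoint_spec <- function(method, url, concept, params = list(),
                          concept_iris = NULL, example = NULL) {
  e <- list(method = method, url = url, concept = concept)
  if (!is.null(concept_iris)) e$concept_iris <- as.list(concept_iris)
  e$params <- params
  if (!is.null(example)) e$example <- example
  e
}

#' Construct and validate a breadcrumb document
#'
#' Assembles the raw mapping and runs it through [validate_document()], so
#' the returned object always satisfies the format's invariants.
#'
#' @param service_name,service_version Service identity (both required,
#'   non-empty).
#' @param mcp_available Logical: does the service expose a native MCP
#'   endpoint?
#' @param redirect_url Absolute URL of the native MCP endpoint; required
#'   when `mcp_available` is `TRUE`.
#' @param endpoints List of [endpoint_spec()] entries. May be empty only
#'   when `mcp_available` is `TRUE`.
#' @return A validated `breadcrumb_document`.
#' @export
breadcrumb_document <- function(service_name, service_version,
                                mcp_available = FALSE, redirect_url = NULL,
                                endpoints = list()) {
  raw <- list(
    service = list(name = service_name, version = service_version),
    mcp_available = c(
      list(status = mcp_available),
      if (!is.null(redirect_url)) list(redirect_url = redirect_url)
    ),
    endpoints = endpoints
  )
  validate_document(raw)
}

# -- validation ----------------------------------------------------------

# Walks the raw mapping collecting every violated field path; returns
# character(0) when the document is structurally valid.
collect_violations <- function(raw) {
  paths <- character(0)
  bad <- function(p) paths <<- c(paths, p)

  if (!is.list(raw) || (length(raw) > 0L && is.null(names(raw)))) {
    return("(document)")
  }

  svc <- raw$service
  if (!is.list(svc)) {
    bad("service")
  } else {
    if (!is_nonempty_string(svc$name)) bad("service.name")
    if (!is_nonempty_string(svc$version)) bad("service.version")
  }

  status <- FALSE
  mcp <- raw$mcp_available
  if (!is.list(mcp) || !is_flag(mcp$status)) {
    bad("mcp_available.status")
  } else {
    status <- mcp$status
    if (isTRUE(status) && !is_absolute_url(mcp$redirect_url)) {
      bad("mcp_available.redirect_url")
    }
    if (!is.null(mcp$redirect_url) && !is_absolute_url(mcp$redirect_url)) {
      bad("mcp_available.redirect_url")
    }
  }

  eps <- raw$endpoints
  if (is.null(eps)) eps <- list()
  if (!is.list(eps) || (length(eps) > 0L && !is.null(names(eps)))) {
    bad("endpoints")
    eps <- list()
  } else if (length(eps) == 0L && !isTRUE(status)) {
    # endpoints may be empty only when a native MCP endpoint exists
    bad("endpoints")
  }

  for (i in seq_along(eps)) {
    e <- eps[[i]]
    pfx <- sprintf("endpoints[%d]", i)
    if (!is.list(e)) {
      bad(pfx)
      next
    }
    if (!is_string(e$method) || !(e$method %in% BC_METHODS)) {
      bad(paste0(pfx, ".method"))
    }
    if (!(is_absolute_url(e$url) || is_root_relative_url(e$url))) {
      bad(paste0(pfx, ".url"))
    }
    if (!is_nonempty_string(e$concept)) bad(paste0(pfx, ".concept"))
    if (!is.null(e$concept_iris)) {
      iris <- e$concept_iris
      ok <- is.list(iris) && is.null(names(iris)) &&
        all(vapply(iris, is_nonempty_string, logical(1)))
      if (!ok) bad(paste0(pfx, ".concept_iris"))
    }
    if (!is.null(e$example) && !is_string(e$example)) {
      bad(paste0(pfx, ".example"))
    }
    ps <- e$params
    if (is.null(ps)) ps <- list()
    if (!is.list(ps) || (length(ps) > 0L && !is.null(names(ps)))) {
      bad(paste0(pfx, ".params"))
      ps <- list()
    }
    seen <- character(0)
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      ppfx <- sprintf("%s.params[%d]", pfx, j)
      if (!is.list(p)) {
        bad(ppfx)
        next
      }
      if (!is_string(p$name) || !grepl("^[A-Za-z_][A-Za-z0-9_]*$", p$name)) {
        bad(paste0(ppfx, ".name"))
      } else {
        if (p$name %in% seen) bad(paste0(pfx, ".params"))
        seen <- c(seen, p$name)
      }
      if (!is_string(p$value_type) || !(p$value_type %in% BC_VALUE_TYPES)) {
        bad(paste0(ppfx, ".value_type"))
      }
      if (!is_flag(p$required)) bad(paste0(ppfx, ".required"))
      if (!is.null(p$description) && !is_string(p$description)) {
        bad(paste0(ppfx, ".description"))
      }
    }
  }

  unique(paths)
}

# Rebuilds the document in canonical field order with optional fields
# dropped when absent, so that identical() is a meaningful equality.
canonicalize_document <- function(raw) {
  mcp <- list(status = isTRUE(raw$mcp_available$status))
  if (!is.null(raw$mcp_available$redirect_url)) {
    mcp$redirect_url <- raw$mcp_available$redirect_url
  }
  eps <- lapply(raw$endpoints %||% list(), function(e) {
    out <- list(method = e$method, url = e$url, concept = e$concept)
    if (!is.null(e$concept_iris)) {
      out$concept_iris <- lapply(e$concept_iris, as.character)
    }
    out$params <- lapply(e$params %||% list(), function(p) {
      pp <- list(
        name = p$name,
        value_type = p$value_type,
        required = isTRUE(p$required)
      )
      if (!is.null(p$description)) pp$description <- p$description
      pp
    })
    if (!is.null(e$example)) out$example <- e$example
    out
  })
  structure(
    list(
      service = list(
        name = raw$service$name,
        version = raw$service$version
      ),
      mcp_available = mcp,
      endpoints = eps
    ),
    class = "breadcrumb_document"
  )
}

#' Validate a raw mapping as a breadcrumb document
#'
#' All-or-nothing schema validation: either every field satisfies the
#' format's invariants and a fully-typed `breadcrumb_document` is returned,
#' or a `bc_validation_error` is signalled whose `paths` field names *every*
#' violated field path (e.g. `"service.name"`, `"endpoints[2].method"`;
#' indices are 1-based). No partial document is ever produced. Unknown extra
#' fields are ignored for forward compatibility.
#'
#' @param raw A named list (as produced by parsing the JSON payload), or a
#'   JSON string which is parsed first. Unparseable JSON is reported as a
#'   violation of path `"(json)"`.
#' @return A `breadcrumb_document` (classed list with `service`,
#'   `mcp_available`, `endpoints`).
#' @seealso [render_comment()], [extract_candidates()]
#' @export
validate_document <- function(raw) {
  if (is.character(raw)) {
    raw <- tryCatch(parse_json(raw), error = function(e) NULL)
    if (is.null(raw)) stop_validation("(json)", "payload is not parseable JSON")
  }
  if (inherits(raw, "breadcrumb_document")) raw <- unclass(raw)
  paths <- collect_violations(raw)
  if (length(paths) > 0L) stop_validation(paths)
  canonicalize_document(raw)
}

#' @export
print.breadcrumb_document <- function(x, ...) {
  cat(sprintf(
    "<breadcrumb_document> %s %s | mcp_available: %s | %d endpoint(s)\n",
    x$service$name, x$service$version,
    if (isTRUE(x$mcp_available$status)) "true" else "false",
    length(x$endpoints)
  ))
  for (e in x$endpoints) {
    cat(sprintf("  %s %s [%s]\n", e$method, e$url, e$concept))
  }
  invisible(x)
}

#' Render a breadcrumb document as an HTML comment
#'
#' Serializes the document to canonical JSON and wraps it in an HTML comment
#' marked with the `mcp-breadcrumb` sentinel. Comment-terminator sequences
#' (`-->`) occurring inside JSON strings are escaped with a JSON unicode
#' escape (`--\u003e`) so the
#' payload can never terminate the comment early; extraction plus JSON
#' parsing recovers the original string.
#'
#' @param doc A validated `breadcrumb_document`.
#' @return A single string: the HTML comment ready for embedding in a page.
#' @export
render_comment <- function(doc) {
  doc <- validate_document(doc)
  json <- canonical_json(unclass(doc))
  esc <- gsub("-->", "--\\\\u003e", json)
  if (grepl("-->", esc, fixed = TRUE)) {
    stop_serialization("payload still contains a comment terminator after escaping")
  }
  paste0("<!-- ", BC_SENTINEL, "\n", esc, "\n-->")
}

#' Extract breadcrumb payloads from page text
#'
#' Scans arbitrary text (well-formed markup not required) for HTML comments
#' whose first token is the `mcp-breadcrumb` sentinel and returns their
#' payloads in document order. This is a total function: it never raises,
#' and returns `character(0)` when no breadcrumb comment is present.
#'
#' @param html Page text (a character vector is collapsed with newlines).
#' @return Character vector of payload texts (the JSON between sentinel and
#'   comment terminator, whitespace-trimmed), possibly empty.
#' @export
extract_candidates <- function(html) {
  if (!is.character(html) || length(html) == 0L) return(character(0))
  html <- paste(html[!is.na(html)], collapse = "\n")
  pat <- paste0("<!--[ \t\r\n]*", BC_SENTINEL, "\\b([\\s\\S]*?)-->")
  m <- tryCatch(
    regmatches(html, gregexpr(pat, html, perl = TRUE))[[1]],
    error = function(e) character(0)
  )
  if (length(m) == 0L) return(character(0))
  payload <- sub(paste0("^<!--[ \t\r\n]*", BC_SENTINEL), "", m, perl = TRUE)
  payload <- sub("-->$", "", payload)
  trimws(payload)
}
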