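# Discovery service over the breadcrumb format: graceful-degradation
# decision ladder, HTTP fetch with bounded retry, direct endpoint execution
# and endpoint enumeration.

#' Discovery outcome constructors
#'
#' A discovery outcome is a tagged union with exactly one variant:
#' `mcp_redirect` (the service has a native MCP endpoint; use it),
#' `api_specification` (no native MCP, but a valid breadcrumb API
#' specification was found), `manual_exploration_required` (no breadcrumbs
#' at all), or `discovery_error` (breadcrumbs present but invalid, or the
#' fetch itself failed). `cause` categorizes errors: `"validation"`,
#' `"network"`, `"timeout"`, `"http"`.
#'
#' @param variant One of the four variant names.
#' @param ... Variant fields (`redirect_url`, `recommendation`, `document`,
#'   `rendered_docs`, `message`, `cause`, `warnings`).
#' @return A `discovery_outcome` object.
#' @export
discovery_outcome <- function(variant = c(
                                "mcp_redirect", "api_specification",
                                "manual_exploration_required", "discovery_error"
                              ), ...) {
  variant <- match.arg(variant)
  structure(list(variant = variant, ...), class = "discovery_outcome")
}

#' @export
print.discovery_outcome <- function(x, ...) {
  cat("<discovery_outcome>", x$variant, "\n")
  if (!is.null(x$message)) cat(" ", x$message, "\n")
  if (!is.null(x$redirect_url)) cat("  redirect:", x$redirect_url, "\n")
  if (!is.null(x$rendered_docs)) cat(x$rendered_docs, "\n")
  invisible(x)
}

# Deterministic plain-text API documentation: one endpoint per line with
# method, url, concept and the parameter signature (required marked "*").
render_endpoint_docs <- function(doc) {
  header <- sprintf(
    "Service: %s %s (no native MCP; fallback API specification)",
    doc$service$name, doc$service$version
  )
  lines <- vapply(doc$endpoints, function(e) {
    sig <- vapply(e$params, function(p) {
      paste0(p$name, if (isTRUE(p$required)) "*" else "", "(", p$value_type, ")")
    }, character(1))
    sprintf(
      "%s %s [%s] params: %s", e$method, e$url, e$concept,
      if (length(sig)) paste(sig, collapse = ", ") else "none"
    )
  }, character(1))
  paste(c(header, lines), collapse = "\n")
}

#' Decide a discovery outcome from a fetch result
#'
#' Pure decision function implementing the graceful-degradation ladder: if
#' the page advertises a native MCP endpoint, redirect there; else if it
#' carries a valid breadcrumb API specification, expose it; if no
#' breadcrumbs are present, indicate that manual exploration is required;
#' if breadcrumbs are present but malformed, return an informative error
#' (never a silent failure). Fetch failures map to `discovery_error` with
#' the corresponding cause.
#'
#' When a page carries several breadcrumb comments, the first valid
#' document wins and later ones are surfaced in the outcome's `warnings`.
#'
#' @param fetch A fetch result: either
#'   `list(ok = TRUE, status = <int>, text = <page>)` or
#'   `list(ok = FALSE, cause = <category>, message = <text>)`.
#' @return A [discovery_outcome()].
#' @export
decide <- function(fetch) {
  if (!isTRUE(fetch$ok)) {
    return(discovery_outcome("discovery_error",
      message = fetch$message %||% "fetch failed",
      cause = fetch$cause %||% "network"
    ))
  }
  if (!is.null(fetch$status) && fetch$status >= 400) {
    return(discovery_outcome("discovery_error",
      message = sprintf("service answered HTTP %d", fetch$status),
      cause = "http"
    ))
  }
  candidates <- extract_candidates(fetch$text)
  if (length(candidates) == 0L) {
    return(discovery_outcome("manual_exploration_required",
      message = paste(
        "No breadcrumb metadata found on this page;",
        "manual exploration required."
      )
    ))
  }
  doc <- NULL
  errors <- character(0)
  warnings <- character(0)
  for (i in seq_along(candidates)) {
    res <- tryCatch(validate_document(candidates[[i]]), error = function(e) e)
    if (inherits(res, "breadcrumb_document")) {
      if (is.null(doc)) {
        doc <- res
      } else {
        warnings <- c(warnings, sprintf(
          "breadcrumb %d ignored: first valid document wins", i
        ))
      }
    } else {
      errors <- c(errors, sprintf("breadcrumb %d: %s", i, conditionMessage(res)))
    }
  }
  if (is.null(doc)) {
    return(discovery_outcome("discovery_error",
      message = paste(
        "Breadcrumb metadata present but invalid:",
        paste(errors, collapse = "; ")
      ),
      cause = "validation"
    ))
  }
  warnings <- c(warnings, errors)
  if (isTRUE(doc$mcp_available$status)) {
    discovery_outcome("mcp_redirect",
      redirect_url = doc$mcp_available$redirect_url,
      recommendation = sprintf(
        "Service '%s' exposes a native MCP endpoint at %s; use the full MCP integration rather than fallback mechanisms.",
        doc$service$name, doc$mcp_available$redirect_url
      ),
      document = doc,
      warnings = warnings
    )
  } else {
    discovery_outcome("api_specification",
      document = doc,
      rendered_docs = render_endpoint_docs(doc),
      warnings = warnings
    )
  }
}

# Fetch a URL with the discovery policy: deadline, up to 5 HTTP redirects,
# and 2 retries with exponential backoff (0.5 s, 1 s) on connection errors
# and 5xx answers. Returns the fetch-result shape decide() consumes.
fetch_url <- function(url, timeout = 10, retries = 2, backoff = c(0.5, 1),
                      sleep_fn = Sys.sleep) {
  attempt <- 0L
  repeat {
    h <- curl::new_handle(
      timeout = timeout, followlocation = TRUE, maxredirs = 5,
      accept_encoding = "identity"
    )
    res <- tryCatch(curl::curl_fetch_memory(url, handle = h), error = function(e) e)
    if (!inherits(res, "error")) {
      if (res$status_code >= 500 && attempt < retries) {
        attempt <- attempt + 1L
        sleep_fn(backoff[min(attempt, length(backoff))])
        next
      }
      txt <- tryCatch(rawToChar(res$content), error = function(e) "")
      return(list(ok = TRUE, status = res$status_code, text = txt))
    }
    msg <- conditionMessage(res)
    timed_out <- grepl("[Tt]ime.?out|timed out", msg)
    if (!timed_out && attempt < retries) {
      attempt <- attempt + 1L
      sleep_fn(backoff[min(attempt, length(backoff))])
      next
    }
    return(list(
      ok = FALSE,
      cause = if (timed_out) "timeout" else "network",
      message = msg
    ))
  }
}

#' Discover a service's machine-actionable interface
#'
#' Fetches the URL (10 s deadline, up to 5 redirects, two retries with
#' 0.5 s / 1 s backoff on connection errors and 5xx) and applies the
#' graceful-degradation ladder of [decide()].
#'
#' @param url Absolute URL of a service page.
#' @param timeout Deadline in seconds (default 10).
#' @param retries,backoff Retry schedule for transient failures.
#' @return A [discovery_outcome()].
#' @export
discover <- function(url, timeout = 10, retries = 2, backoff = c(0.5, 1)) {
  decide(fetch_url(url, timeout = timeout, retries = retries, backoff = backoff))
}

#' Execute a discovered API endpoint
#'
#' Issues one HTTP request against an endpoint discovered via breadcrumbs.
#' GET and DELETE serialize `params` as URL-encoded query pairs; POST and
#' PUT send them as a JSON body (`Content-Type: application/json`). The raw
#' result is returned without interpretation — authentication challenges
#' (401/403) come back verbatim, since breadcrumbs document but cannot
#' perform authentication.
#'
#' @param url Endpoint URL (absolute).
#' @param method One of GET, POST, PUT, DELETE; anything else signals
#'   `bc_unsupported_method_error`.
#' @param params Named list of parameters.
#' @param timeout Deadline in seconds (default 30); signals
#'   `bc_timeout_error` when exceeded.
#' @return An `http_result`: `status_code`, `headers` (named list), `body`
#'   (raw), `text` (decoded when possible), `elapsed` (seconds).
#' @export
execute_endpoint <- function(url, method, params = list(), timeout = 30) {
  if (!is_string(method) || !(method %in% BC_METHODS)) {
    stop_unsupported_method(method)
  }
  h <- curl::new_handle(timeout = timeout, customrequest = method)
  if (method %in% c("GET", "DELETE")) {
    url <- append_query(url, params)
  } else {
    body <- canonical_json(params)
    curl::handle_setopt(h,
      postfields = body,
      copypostfields = body
    )
    curl::handle_setheaders(h, "Content-Type" = "application/json")
  }
  t0 <- monotonic_now()
  res <- tryCatch(curl::curl_fetch_memory(url, handle = h), error = function(e) e)
  if (inherits(res, "error")) {
    msg <- conditionMessage(res)
    if (grepl("[Tt]ime.?out|timed out", msg)) {
      stop_timeout(sprintf("request to %s exceeded the %ds deadline", url, timeout))
    }
    stop(res)
  }
  structure(
    list(
      status_code = res$status_code,
      headers = curl::parse_headers_list(res$headers),
      body = res$content,
      text = tryCatch(rawToChar(res$content), error = function(e) NULL),
      elapsed = monotonic_now() - t0
    ),
    class = "http_result"
  )
}

#' Enumerate a service's discovered endpoints
#'
#' Projection of [discover()]: when the ladder yields an API specification,
#' returns one record per endpoint (method, url, concept) in document
#' order; for every other variant an empty list is returned together with
#' an explanatory note.
#'
#' @inheritParams discover
#' @return A list with `endpoints` (list of `list(method, url, concept)`)
#'   and `note` (non-`NULL` for the non-specification variants).
#' @export
list_endpoints <- function(url, timeout = 10) {
  out <- discover(url, timeout = timeout)
  if (out$variant == "api_specification") {
    eps <- lapply(out$document$endpoints, function(e) {
      list(method = e$method, url = e$url, concept = e$concept)
    })
    list(endpoints = eps, note = NULL)
  } else {
    note <- switch(out$variant,
      mcp_redirect = sprintf(
        "Native MCP endpoint available at %s; no fallback endpoints needed.",
        out$redirect_url
      ),
      manual_exploration_required = out$message,
      discovery_error = out$message
    )
    list(endpoints = list(), note = note)
  }
}
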