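# MCP transports: a standard-stream JSON-RPC transport and an HTTP mode
# with an OpenAPI description, CORS, a server-sent-event stream for
# download progress, and a health probe. Both transports expose identical
# tool registries.

MCP_PROTOCOL_VERSION <- "2024-11-05"

strip_classes <- function(x) {
  if (is.list(x)) {
    attr(x, "class") <- NULL
    lapply(x, strip_classes)
  } else {
    x
  }
}

#' Create an MCP tool registry
#'
#' A registry binds tool descriptors to their handler functions; the same
#' registry object is served over both transports, which guarantees
#' identical capability advertisements.
#'
#' @param name,version Server identity reported during capability
#'   negotiation.
#' @param tools Named list; each element is
#'   `list(descriptor = <tool_descriptor>, handler = function(arguments))`
#'   where the handler returns a `tool_response`.
#' @param manager Optional [download_manager()] backing the event stream
#'   and download tools.
#' @param config_warnings Character vector of configuration fallbacks, for
#'   the health probe.
#' @return An `mcp_registry`.
#' @export
mcp_registry <- function(name, version, tools, manager = NULL,
                         config_warnings = character(0)) {
  stopifnot(length(tools) > 0, !is.null(names(tools)))
  structure(
    list(
      name = name, version = version, tools = tools, manager = manager,
      config_warnings = config_warnings
    ),
    class = "mcp_registry"
  )
}

descriptor_json <- function(d) {
  list(
    name = d$name,
    description = d$description,
    inputSchema = d$input_schema,
    outputSchema = d$output_schema,
    concepts = d$concepts
  )
}

#' The GEO server registry
#'
#' Binds the eight GEO tool descriptors ([geo_list_tools()]) to live
#' handlers over the E-utilities client and the download manager.
#'
#' @param cfg An [eutils_config()].
#' @param policy A [download_policy()]; defaults to one rooted at
#'   `cfg$download_dir`.
#' @return An `mcp_registry` with exactly eight tools.
#' @export
geo_registry <- function(cfg = eutils_config(),
                         policy = download_policy(path.expand(cfg$download_dir))) {
  manager <- download_manager(policy, cfg)
  descriptors <- geo_list_tools()
  names(descriptors) <- vapply(descriptors, function(d) d$name, character(1))
  tools <- lapply(descriptors, function(d) {
    nm <- d$name
    handler <-
      if (nm %in% GEO_SEARCH_TOOLS) {
        function(args) {
          run_search_tool(nm, args$term, args$retmax %||% RETMAX_DEFAULT, cfg)
        }
      } else if (nm == "download_geo_data") {
        function(args) {
          res <- tryCatch({
            job_id <- download_geo_data(manager, args$accession,
                                        wait = args$wait %||% TRUE)
            st <- get_download_status(manager, job_id)[[1]]
            wrap_response(
              c(st, list(tool = "download_geo_data")),
              summary = sprintf("download %s: %s", args$accession, st$state)
            )
          }, biocrumbs_error = function(e) {
            wrap_response(
              list(tool = "download_geo_data", error = conditionMessage(e)),
              summary = sprintf("download failed: %s", conditionMessage(e)),
              is_error = TRUE
            )
          })
          res
        }
      } else {
        function(args) {
          jobs <- get_download_status(manager, args$job_id)
          wrap_response(
            list(tool = "get_download_status", jobs = jobs),
            summary = sprintf("%d job(s)", length(jobs))
          )
        }
      }
    list(descriptor = d, handler = handler)
  })
  mcp_registry("geo-mcp", "0.1.0", tools,
               manager = manager, config_warnings = cfg$warnings)
}

#' The breadcrumbs discovery server registry
#'
#' The three-tool discovery service: `discover_service` applies the
#' graceful-degradation ladder to a URL, `execute_endpoint` performs a
#' direct request against a discovered endpoint, and `list_endpoints`
#' enumerates endpoints for multi-step workflows.
#'
#' @param discovery_timeout Fetch deadline for discovery requests
#'   (seconds, default 10).
#' @param executor_timeout Deadline for endpoint execution (seconds,
#'   default 30).
#' @return An `mcp_registry` with exactly three tools.
#' @export
breadcrumbs_registry <- function(discovery_timeout = 10,
                                 executor_timeout = 30) {
  url_only_schema <- list(
    type = "object",
    properties = list(
      url = list(type = "string", description = "Absolute URL of a service page.")
    ),
    required = list("url")
  )
  tools <- list(
    discover_service = list(
      descriptor = tool_descriptor(
        name = "discover_service",
        description = "Fetch a service page, extract embedded breadcrumb metadata, and report the best integration path: native MCP redirect, fallback API specification, or manual exploration.",
        input_schema = url_only_schema,
        output_schema = list(
          type = "object",
          properties = list(
            variant = list(
              type = "string",
              enum = list("mcp_redirect", "api_specification",
                          "manual_exploration_required", "discovery_error")
            )
          ),
          required = list("variant")
        ),
        concepts = list("service_discovery")
      ),
      handler = function(args) {
        out <- discover(args$url, timeout = discovery_timeout)
        wrap_response(
          strip_classes(unclass(out)),
          summary = sprintf("discovery of %s: %s", args$url, out$variant)
        )
      }
    ),
    execute_endpoint = list(
      descriptor = tool_descriptor(
        name = "execute_endpoint",
        description = "Issue a direct HTTP request against a discovered endpoint. GET/DELETE parameters are URL-encoded; POST/PUT parameters are sent as a JSON body.",
        input_schema = list(
          type = "object",
          properties = list(
            url = list(type = "string"),
            method = list(type = "string",
                          enum = as.list(BC_METHODS)),
            params = list(type = "object", default = structure(list(), names = character(0))),
            timeout = list(type = "integer", default = executor_timeout)
          ),
          required = list("url", "method")
        ),
        output_schema = list(
          type = "object",
          properties = list(
            status_code = list(type = "integer"),
            text = list(type = "string")
          ),
          required = list("status_code")
        ),
        concepts = list("api_execution")
      ),
      handler = function(args) {
        res <- tryCatch(
          execute_endpoint(args$url, args$method, args$params %||% list(),
                           timeout = args$timeout %||% executor_timeout),
          biocrumbs_error = function(e) e
        )
        if (inherits(res, "biocrumbs_error")) {
          return(wrap_response(
            list(error = conditionMessage(res), error_class = class(res)[1]),
            summary = sprintf("request failed: %s", conditionMessage(res)),
            is_error = TRUE
          ))
        }
        wrap_response(
          list(status_code = res$status_code, headers = res$headers,
               text = res$text, elapsed = res$elapsed),
          summary = sprintf("%s %s -> HTTP %d", args$method, args$url,
                            res$status_code)
        )
      }
    ),
    list_endpoints = list(
      descriptor = tool_descriptor(
        name = "list_endpoints",
        description = "Quick enumeration of a service's discovered endpoints (method, url, concept) for multi-step workflows.",
        input_schema = url_only_schema,
        output_schema = list(
          type = "object",
          properties = list(
            endpoints = list(type = "array"),
            note = list(type = "string")
          ),
          required = list("endpoints")
        ),
        concepts = list("endpoint_enumeration")
      ),
      handler = function(args) {
        out <- list_endpoints(args$url, timeout = discovery_timeout)
        wrap_response(
          list(endpoints = out$endpoints, note = out$note),
          summary = sprintf("%d endpoint(s)%s", length(out$endpoints),
                            if (is.null(out$note)) "" else " (see note)")
        )
      }
    )
  )
  mcp_registry("breadcrumbs-mcp", "0.1.0", tools)
}

#' Health probe
#'
#' Reports liveness, registry size and configuration-load state; a registry
#' that failed to load yields a degraded (but alive) report.
#'
#' @param registry An [mcp_registry()], or `NULL` if registry loading
#'   failed.
#' @return A status record list.
#' @export
health <- function(registry) {
  if (is.null(registry) || length(registry$tools) == 0L) {
    return(list(status = "degraded", tools = 0L,
                message = "tool registry unavailable"))
  }
  out <- list(
    status = "ok",
    server = registry$name,
    tools = length(registry$tools),
    config_fallback = length(registry$config_warnings) > 0L
  )
  if (length(registry$config_warnings) > 0L) {
    out$config_warnings <- as.list(registry$config_warnings)
  }
  out
}

# -- JSON-RPC framing ----------------------------------------------------

rpc_result <- function(id, result) {
  canonical_json(list(jsonrpc = "2.0", id = id, result = result))
}

rpc_error <- function(id, code, message) {
  canonical_json(list(
    jsonrpc = "2.0", id = id,
    error = list(code = code, message = message)
  ))
}

tool_call_result <- function(response) {
  list(
    content = lapply(response$content, function(b) {
      list(type = b$type, text = b$text, summary = b$summary, json = b$json)
    }),
    isError = isTRUE(response$is_error)
  )
}

call_tool <- function(registry, name, arguments) {
  tool <- registry$tools[[name]]
  if (is.null(tool)) return(NULL)
  response <- tryCatch(
    tool$handler(arguments %||% list()),
    error = function(e) {
      wrap_response(
        list(tool = name, error = conditionMessage(e)),
        summary = sprintf("tool '%s' failed: %s", name, conditionMessage(e)),
        is_error = TRUE
      )
    }
  )
  tool_call_result(response)
}

#' Handle one JSON-RPC frame
#'
#' Processes a single MCP frame (`initialize`, `tools/list`, `tools/call`,
#' `ping`, notifications) and returns the response as a JSON string, or
#' `NULL` for notifications. Malformed frames are answered with
#' protocol-level errors (`-32700` parse error, `-32600` invalid request,
#' `-32601` unknown method, `-32602` unknown tool) — never an R error, so
#' a hostile frame cannot take the server down.
#'
#' @param registry An [mcp_registry()].
#' @param line One frame of newline-delimited JSON-RPC text.
#' @return JSON response string or `NULL`.
#' @export
handle_frame <- function(registry, line) {
  msg <- tryCatch(parse_json(line), error = function(e) NULL)
  if (is.null(msg) || !is.list(msg)) {
    return(rpc_error(NULL, -32700L, "parse error: frame is not valid JSON"))
  }
  id <- msg$id
  method <- msg$method
  if (!is_string(method)) {
    return(rpc_error(id, -32600L, "invalid request: missing method"))
  }
  if (startsWith(method, "notifications/")) return(NULL)
  switch(method,
    initialize = rpc_result(id, list(
      protocolVersion = MCP_PROTOCOL_VERSION,
      capabilities = list(tools = structure(list(), names = character(0))),
      serverInfo = list(name = registry$name, version = registry$version)
    )),
    ping = rpc_result(id, structure(list(), names = character(0))),
    "tools/list" = rpc_result(id, list(
      tools = unname(lapply(registry$tools, function(t) descriptor_json(t$descriptor)))
    )),
    "tools/call" = {
      name <- msg$params$name
      if (!is_string(name)) {
        return(rpc_error(id, -32602L, "invalid params: tool name missing"))
      }
      res <- call_tool(registry, name, msg$params$arguments)
      if (is.null(res)) {
        rpc_error(id, -32602L, sprintf("unknown tool '%s'", name))
      } else {
        rpc_result(id, res)
      }
    },
    rpc_error(id, -32601L, sprintf("method '%s' not found", method))
  )
}

#' Serve a registry over standard streams
#'
#' The MCP stdio transport: newline-delimited JSON-RPC frames are read
#' from `input` and answered on `output` until the input stream closes.
#' Capability advertisement (`initialize`) precedes tool calls; malformed
#' frames get protocol errors and never terminate the process.
#'
#' @param registry An [mcp_registry()].
#' @param input,output Connections (default the process standard streams).
#' @return Number of frames handled, invisibly (on input close).
#' @export
serve_stdio <- function(registry, input = stdin(), output = stdout()) {
  n <- 0L
  repeat {
    line <- tryCatch(readLines(input, n = 1L, warn = FALSE),
                     error = function(e) character(0))
    if (length(line) == 0L) break
    if (!nzchar(trimws(line))) next
    n <- n + 1L
    resp <- handle_frame(registry, line)
    if (!is.null(resp)) {
      writeLines(resp, con = output)
      flush(output)
    }
  }
  invisible(n)
}

# -- HTTP transport ------------------------------------------------------

parse_query <- function(qs) {
  qs <- sub("^\\?", "", qs %||% "")
  if (!nzchar(qs)) return(list())
  pairs <- strsplit(qs, "&", fixed = TRUE)[[1]]
  out <- list()
  for (p in pairs) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) >= 1L && nzchar(kv[1])) {
      out[[httpuv::decodeURIComponent(kv[1])]] <-
        httpuv::decodeURIComponent(paste(kv[-1], collapse = "="))
    }
  }
  out
}

cors_headers <- function(extra = list()) {
  c(
    list(
      "Access-Control-Allow-Origin" = "*",
      "Access-Control-Allow-Methods" = "GET, POST, OPTIONS",
      "Access-Control-Allow-Headers" = "Content-Type"
    ),
    extra
  )
}

http_json <- function(status, payload) {
  list(
    status = as.integer(status),
    headers = cors_headers(list("Content-Type" = "application/json")),
    body = canonical_json(payload)
  )
}

openapi_document <- function(registry) {
  paths <- lapply(registry$tools, function(t) {
    d <- t$descriptor
    list(post = list(
      operationId = d$name,
      summary = d$description,
      requestBody = list(content = list(
        "application/json" = list(schema = d$input_schema)
      )),
      responses = list("200" = list(
        description = "MCP tool response",
        content = list("application/json" = list(schema = d$output_schema))
      ))
    ))
  })
  names(paths) <- paste0("/tools/", names(registry$tools))
  list(
    openapi = "3.0.3",
    info = list(title = registry$name, version = registry$version),
    paths = paths
  )
}

# Bounded server-sent-event stream for one download job: progress events
# collected while the transfer pool is driven, then a terminal event. The
# full event-stream body is returned once the job reaches a terminal
# state (or the deadline passes), keeping the route deterministic.
sse_events <- function(registry, job_id, deadline = 30) {
  manager <- registry$manager
  if (is.null(manager)) return(NULL)
  terminal <- c("completed", "failed", "rejected", "not_found")
  events <- character(0)
  emit <- function(type, payload) {
    events <<- c(events, sprintf("event: %s\ndata: %s\n\n",
                                 type, canonical_json(payload)))
  }
  t0 <- monotonic_now()
  last_emit <- -Inf
  repeat {
    st <- get_download_status(manager, job_id)[[1]]
    if (st$state %in% terminal) {
      emit("progress", st)
      emit("done", st)
      break
    }
    if (monotonic_now() - last_emit >= 1 || length(events) == 0L) {
      emit("progress", st)
      last_emit <- monotonic_now()
    }
    if (monotonic_now() - t0 > deadline) {
      emit("timeout", st)
      break
    }
    manager_poll(manager, timeout = 0.2)
  }
  paste(events, collapse = "")
}

#' Build the HTTP (REST) application for a registry
#'
#' One POST route per tool (`/tools/<name>`, JSON body mirroring the
#' tool's input schema), `GET /tools` for enumeration, an OpenAPI
#' description at `/openapi.json`, a health probe at `/health`, a
#' server-sent-event stream for download progress at
#' `/events?job_id=<id>`, and permissive CORS on every response
#' (preflight `OPTIONS` included). Unknown tool routes answer 404 with a
#' structured error; malformed requests get structured per-request errors.
#'
#' @param registry An [mcp_registry()].
#' @return An app object suitable for [httpuv::startServer()].
#' @export
http_app <- function(registry) {
  list(call = function(req) {
    tryCatch({
      method <- req$REQUEST_METHOD
      path <- req$PATH_INFO
      if (method == "OPTIONS") {
        # preflight; 200 rather than 204 keeps keep-alive framing simple
        return(list(
          status = 200L,
          headers = cors_headers(list("Content-Type" = "text/plain")),
          body = ""
        ))
      }
      if (path == "/__ping") {
        return(list(status = 200L, headers = cors_headers(), body = "ok"))
      }
      if (path == "/health") {
        return(http_json(200L, health(registry)))
      }
      if (path == "/openapi.json") {
        return(http_json(200L, openapi_document(registry)))
      }
      if (path == "/tools" && method == "GET") {
        return(http_json(200L, list(
          tools = unname(lapply(registry$tools,
                                function(t) descriptor_json(t$descriptor)))
        )))
      }
      if (path == "/events") {
        q <- parse_query(req$QUERY_STRING)
        if (is.null(q$job_id)) {
          return(http_json(400L, list(error = "job_id query parameter required")))
        }
        body <- sse_events(registry, q$job_id)
        if (is.null(body)) {
          return(http_json(404L, list(error = "no download manager attached")))
        }
        return(list(
          status = 200L,
          headers = cors_headers(list(
            "Content-Type" = "text/event-stream",
            "Cache-Control" = "no-cache"
          )),
          body = body
        ))
      }
      if (startsWith(path, "/tools/") && method == "POST") {
        name <- sub("^/tools/", "", path)
        raw <- req$rook.input$read()
        args <- if (length(raw) == 0L) list() else {
          tryCatch(parse_json(rawToChar(raw)), error = function(e) NULL)
        }
        if (is.null(args)) {
          return(http_json(400L, list(error = "request body is not valid JSON")))
        }
        res <- call_tool(registry, name, args)
        if (is.null(res)) {
          return(http_json(404L, list(error = sprintf("unknown tool '%s'", name))))
        }
        return(http_json(200L, res))
      }
      http_json(404L, list(error = sprintf("no route %s %s", method, path)))
    }, error = function(e) {
      http_json(500L, list(error = conditionMessage(e)))
    })
  })
}

#' Serve a registry over HTTP
#'
#' Blocking HTTP server mode (see [http_app()] for the routes). Both
#' transports serve the same registry object, so stdio and HTTP expose
#' identical tool descriptors and payload-identical tool results.
#'
#' @param registry An [mcp_registry()].
#' @param port TCP port.
#' @param host Bind address.
#' @return Does not return under normal operation (runs the event loop).
#' @export
serve_http <- function(registry, port, host = "127.0.0.1") {
  httpuv::runServer(host, port, http_app(registry))
}
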