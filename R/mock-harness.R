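# Offline mock-service harness: deterministic breadcrumb fixture pages for
# the four validation scenarios, a scripted E-utilities emulator, a
# controllable file server (spoofable Content-Length, per-file delays,
# concurrency instrumentation) and an echo server. Servers run in a
# background R process so client code in the foreground session can block
# on them freely.

#' A small fixture breadcrumb document
#'
#' Two-endpoint demo service used by the scenario pages and round-trip
#' tests: a search endpoint (`search_data`) and a download endpoint
#' (`download_file`).
#'
#' @return A validated `breadcrumb_document`.
#' @export
sample_document <- function() {
  breadcrumb_document(
    service_name = "demo-service", service_version = "1.2.0",
    mcp_available = FALSE,
    endpoints = list(
      endpoint_spec(
        "GET", "/api/search", "search_data",
        params = list(
          param_spec("gene", "string", required = TRUE,
                     description = "Gene symbol to query."),
          param_spec("limit", "integer", required = FALSE)
        ),
        example = "/api/search?gene=BDNF&limit=5"
      ),
      endpoint_spec(
        "GET", "/api/download", "download_file",
        params = list(param_spec("id", "string", required = TRUE))
      )
    )
  )
}

wrap_html <- function(inner) {
  paste0(
    "<html><head><title>Demo Service</title></head><body>\n",
    "<h1>Demo Service</h1>\n<p>Interactive exploration portal.</p>\n",
    inner,
    "\n</body></html>\n"
  )
}

#' Build a fixture page for one discovery scenario
#'
#' The scenario matrix used throughout validation: `none` (no breadcrumb
#' comment at all), `valid` (a well-formed two-endpoint breadcrumb),
#' `malformed` (sentinel comment whose payload is not valid JSON),
#' `redirect` (`mcp_available.status: true` with a redirect URL and no
#' fallback endpoints), plus the `hybrid` extension (valid endpoints *and*
#' native MCP availability) used to verify that redirect dominates the
#' degradation ladder. Page text is deterministic per kind.
#'
#' @param kind One of `"none"`, `"valid"`, `"malformed"`, `"redirect"`,
#'   `"hybrid"`.
#' @return A `scenario`: `list(kind, page, expected_outcome)` where
#'   `expected_outcome` names the discovery-outcome variant the ladder
#'   must produce.
#' @export
build_page <- function(kind = c("none", "valid", "malformed", "redirect", "hybrid")) {
  kind <- match.arg(kind)
  page <- switch(kind,
    none = wrap_html("<!-- just an ordinary comment -->"),
    valid = wrap_html(render_comment(sample_document())),
    malformed = wrap_html(paste0(
      "<!-- ", BC_SENTINEL, "\n",
      "{\"service\": {\"name\": \"demo-service\", \"version\":\n",
      "-->"
    )),
    redirect = wrap_html(render_comment(breadcrumb_document(
      service_name = "demo-service", service_version = "1.2.0",
      mcp_available = TRUE,
      redirect_url = "https://demo.example.org/mcp"
    ))),
    hybrid = wrap_html(render_comment(breadcrumb_document(
      service_name = "demo-service", service_version = "1.2.0",
      mcp_available = TRUE,
      redirect_url = "https://demo.example.org/mcp",
      endpoints = sample_document()$endpoints
    )))
  )
  expected <- switch(kind,
    none = "manual_exploration_required",
    valid = "api_specification",
    malformed = "discovery_error",
    redirect = "mcp_redirect",
    hybrid = "mcp_redirect"
  )
  structure(
    list(kind = kind, page = page, expected_outcome = expected),
    class = "scenario"
  )
}

#' The scripted transcript fixture for the E-utilities emulator
#'
#' Encodes the search transcript the suite validates against: several
#' refinement terms that legitimately return empty UID lists, and the
#' successful broad term `"microglia depletion"` whose UID list begins
#' `200299005, 200279739`. The UID-to-accession table (200299005 ->
#' GSE299005 and so on, plus 200271535 -> GSE271535) is a harness
#' convention so every scripted UID resolves in the summary mapping.
#'
#' @param inject Optional list of failure injections, each
#'   `list(route = "esearch"|"esummary", status = <int>, body = <text>,
#'   delay = <seconds>)`, consumed first-in-first-out per route.
#' @return An `eutils_script` list with `terms`, `summaries`, `inject`.
#' @export
default_eutils_script <- function(inject = list()) {
  uids <- c("200299005", "200279739", "200271535", "200270935",
            "200292830", "200288018", "200288504")
  titles <- c(
    "200299005" = "Post-TBI microglia depletion (snRNA-seq)",
    "200279739" = "Microglia depletion time course in mouse brain",
    "200271535" = "Microglia innate immune memory after CSF1R depletion (RNA-seq)",
    "200270935" = "Companion ATAC-seq dataset",
    "200292830" = "PLX3397-mediated depletion with monocyte replacement",
    "200288018" = "Krabbe disease model with microglia replacement",
    "200288504" = "Krabbe disease model with microglia replacement (part 2)"
  )
  summaries <- lapply(uids, function(u) {
    list(
      uid = u,
      accession = paste0("GSE", substring(u, 4)),
      title = unname(titles[[u]]),
      summary = paste("Reference dataset for microglia depletion in mice:",
                      unname(titles[[u]])),
      taxon = "Mus musculus",
      entrytype = "GSE"
    )
  })
  names(summaries) <- uids
  list(
    terms = list(
      "microglia depletion mouse" = list(count = 0, uids = character(0)),
      "microglia PLX3397 mouse" = list(count = 0, uids = character(0)),
      "CSF1R inhibitor mouse brain" = list(count = 0, uids = character(0)),
      "microglia mouse brain" = list(count = 0, uids = character(0)),
      "microglia depletion" = list(count = length(uids), uids = uids)
    ),
    summaries = summaries,
    inject = inject
  )
}

respond_maybe_delayed <- function(response, delay) {
  if (is.null(delay) || delay <= 0) return(response)
  promises::promise(function(resolve, reject) {
    later::later(function() resolve(response), delay = delay)
  })
}

#' Run the scenario page server (blocking)
#'
#' Serves each scenario page at `/<kind>`, a `/flaky` route that answers
#' HTTP 500 for the first `flaky_failures` requests and the valid page
#' afterwards (for retry-schedule tests), a `/slow` route that never
#' responds (for timeout tests), and `/__ping` for readiness probing.
#'
#' @param port TCP port to bind.
#' @param flaky_failures Number of initial 500 answers on `/flaky`.
#' @return Does not return; runs the server loop.
#' @export
run_mock_pages <- function(port, flaky_failures = 2) {
  pages <- lapply(
    c("none", "valid", "malformed", "redirect", "hybrid"),
    function(k) build_page(k)$page
  )
  names(pages) <- c("none", "valid", "malformed", "redirect", "hybrid")
  flaky_left <- flaky_failures
  app <- list(call = function(req) {
    path <- sub("^/", "", req$PATH_INFO)
    if (path == "__ping") {
      return(list(status = 200L, headers = list("Content-Type" = "text/plain"),
                  body = "ok"))
    }
    if (path == "slow") {
      return(promises::promise(function(resolve, reject) NULL))
    }
    if (path == "flaky") {
      if (flaky_left > 0L) {
        flaky_left <<- flaky_left - 1L
        return(list(status = 500L,
                    headers = list("Content-Type" = "text/plain"),
                    body = "transient failure"))
      }
      return(list(status = 200L, headers = list("Content-Type" = "text/html"),
                  body = pages[["valid"]]))
    }
    if (!is.null(pages[[path]])) {
      return(list(status = 200L, headers = list("Content-Type" = "text/html"),
                  body = pages[[path]]))
    }
    list(status = 404L, headers = list("Content-Type" = "text/plain"),
         body = "not found")
  })
  httpuv::runServer("127.0.0.1", port, app)
}

#' Run the scripted E-utilities emulator (blocking)
#'
#' ESearch-shaped and ESummary-shaped routes answer from the script's
#' term and UID mappings (unknown terms yield an empty UID list, the
#' normal upstream behavior); accession lookups of the form
#' `GSExxxx[ACCN]` resolve against the summary table. Failure injections
#' (status code, garbage body, delay) are honored first-in-first-out.
#' `/__log` reports per-route request counts.
#'
#' @param port TCP port to bind.
#' @param script An `eutils_script` (default [default_eutils_script()]).
#' @return Does not return; runs the server loop.
#' @export
run_mock_eutils <- function(port, script = default_eutils_script()) {
  log <- list(esearch = 0L, esummary = 0L)
  inject <- script$inject %||% list()

  take_injection <- function(route) {
    for (i in seq_along(inject)) {
      if (identical(inject[[i]]$route, route)) {
        inj <- inject[[i]]
        inject <<- inject[-i]
        return(inj)
      }
    }
    NULL
  }

  acc_index <- vapply(script$summaries, function(s) s$accession, character(1))

  app <- list(call = function(req) {
    path <- req$PATH_INFO
    q <- parse_query(req$QUERY_STRING)
    if (path == "/__ping") {
      return(list(status = 200L, headers = list("Content-Type" = "text/plain"),
                  body = "ok"))
    }
    if (path == "/__log") {
      return(list(status = 200L,
                  headers = list("Content-Type" = "application/json"),
                  body = canonical_json(log)))
    }
    if (grepl("esearch\\.fcgi$", path)) {
      log$esearch <<- log$esearch + 1L
      inj <- take_injection("esearch")
      if (!is.null(inj)) {
        resp <- list(
          status = as.integer(inj$status %||% 500L),
          headers = list("Content-Type" = "text/plain"),
          body = inj$body %||% "injected failure"
        )
        return(respond_maybe_delayed(resp, inj$delay))
      }
      term <- q$term %||% ""
      hit <- script$terms[[term]]
      if (is.null(hit) && grepl("^(GSE|GSM|GPL|GDS)[0-9]+\\[ACCN\\]$", term)) {
        acc <- sub("\\[ACCN\\]$", "", term)
        uid <- names(acc_index)[acc_index == acc]
        hit <- list(count = length(uid), uids = uid)
      }
      if (is.null(hit)) hit <- list(count = 0, uids = character(0))
      retmax <- suppressWarnings(as.integer(q$retmax %||% "20"))
      uids <- utils::head(hit$uids, retmax)
      body <- canonical_json(list(esearchresult = list(
        count = as.character(hit$count),
        retmax = as.character(retmax),
        idlist = as.list(uids),
        querytranslation = term
      )))
      return(list(status = 200L,
                  headers = list("Content-Type" = "application/json"),
                  body = body))
    }
    if (grepl("esummary\\.fcgi$", path)) {
      log$esummary <<- log$esummary + 1L
      inj <- take_injection("esummary")
      if (!is.null(inj)) {
        resp <- list(
          status = as.integer(inj$status %||% 500L),
          headers = list("Content-Type" = "text/plain"),
          body = inj$body %||% "injected failure"
        )
        return(respond_maybe_delayed(resp, inj$delay))
      }
      ids <- strsplit(q$id %||% "", ",", fixed = TRUE)[[1]]
      result <- list(uids = as.list(ids))
      for (u in ids) {
        if (!is.null(script$summaries[[u]])) {
          result[[u]] <- script$summaries[[u]]
        }
      }
      return(list(status = 200L,
                  headers = list("Content-Type" = "application/json"),
                  body = canonical_json(list(result = result))))
    }
    list(status = 404L, headers = list("Content-Type" = "text/plain"),
         body = "not found")
  })
  httpuv::runServer("127.0.0.1", port, app)
}

#' Run the controllable file server (blocking)
#'
#' Serves `/files/<name>` from the catalog. Each entry may advertise a
#' spoofed `Content-Length` (so size-limit policies can be exercised
#' without materializing multi-gigabyte fixtures), suppress the length
#' header entirely (`advertised = "none"`), and delay its response so the
#' client's concurrency bound becomes observable. `/stats` reports the
#' maximum number of simultaneously in-flight requests and a request
#' count; `HEAD` requests answer the advertised length without a body.
#'
#' @param port TCP port to bind.
#' @param catalog Named list; each element
#'   `list(content = <string>, advertised = <bytes|NA|"none">, delay = <s>)`.
#' @return Does not return; runs the server loop.
#' @export
run_mock_files <- function(port, catalog) {
  active <- 0L
  max_active <- 0L
  requests <- 0L
  app <- list(call = function(req) {
    path <- req$PATH_INFO
    if (path == "/__ping") {
      return(list(status = 200L, headers = list("Content-Type" = "text/plain"),
                  body = "ok"))
    }
    if (path == "/stats") {
      return(list(
        status = 200L, headers = list("Content-Type" = "application/json"),
        body = canonical_json(list(
          max_active = max_active, requests = requests, active = active
        ))
      ))
    }
    if (!startsWith(path, "/files/")) {
      return(list(status = 404L, headers = list("Content-Type" = "text/plain"),
                  body = "not found"))
    }
    name <- sub("^/files/", "", path)
    entry <- catalog[[name]]
    if (is.null(entry)) {
      return(list(status = 404L, headers = list("Content-Type" = "text/plain"),
                  body = "no such file"))
    }
    requests <<- requests + 1L
    content <- entry$content
    if (is.character(content)) content <- charToRaw(paste(content, collapse = ""))
    adv <- entry$advertised
    headers <- list("Content-Type" = "application/octet-stream")
    if (is.null(adv) || (length(adv) == 1L && is.na(adv))) {
      headers[["Content-Length"]] <- as.character(length(content))
    } else if (!identical(adv, "none")) {
      headers[["Content-Length"]] <- sprintf("%.0f", as.numeric(adv))
    }
    if (identical(req$REQUEST_METHOD, "HEAD")) {
      return(list(status = 200L, headers = headers, body = ""))
    }
    delay <- entry$delay %||% 0
    if (delay > 0) {
      active <<- active + 1L
      max_active <<- max(max_active, active)
      return(promises::promise(function(resolve, reject) {
        later::later(function() {
          active <<- active - 1L
          resolve(list(status = 200L, headers = headers, body = content))
        }, delay = delay)
      }))
    }
    list(status = 200L, headers = headers, body = content)
  })
  httpuv::runServer("127.0.0.1", port, app)
}

#' Run the request echo server (blocking)
#'
#' Answers every request with a JSON description of what it received:
#' method, path, decoded query parameters, content type, and the request
#' body. Used to verify parameter-serialization contracts.
#'
#' @param port TCP port to bind.
#' @return Does not return; runs the server loop.
#' @export
run_mock_echo <- function(port) {
  app <- list(call = function(req) {
    if (req$PATH_INFO == "/__ping") {
      return(list(status = 200L, headers = list("Content-Type" = "text/plain"),
                  body = "ok"))
    }
    raw <- tryCatch(req$rook.input$read(), error = function(e) raw(0))
    body <- tryCatch(rawToChar(raw), error = function(e) "")
    payload <- list(
      method = req$REQUEST_METHOD,
      path = req$PATH_INFO,
      query = parse_query(req$QUERY_STRING),
      content_type = req$CONTENT_TYPE %||% "",
      body = body
    )
    list(status = 200L, headers = list("Content-Type" = "application/json"),
         body = canonical_json(payload))
  })
  httpuv::runServer("127.0.0.1", port, app)
}

#' Start a mock service in a background process
#'
#' Launches one of the harness servers (`pages`, `eutils`, `files`,
#' `echo`) — or an MCP HTTP transport (`http`) — in a background R
#' process via `callr`, waits until its readiness probe answers, and
#' returns a handle. The foreground session can then issue blocking
#' client requests against `base_url` without event-loop deadlock.
#'
#' @param kind Which server to run.
#' @param args Named list of arguments passed to the `run_mock_*` /
#'   registry-building function.
#' @param port TCP port; a free ephemeral port is picked by default.
#' @param startup_timeout Seconds to wait for readiness.
#' @return A `mock_server` handle: `base_url`, `port`, `process`, and
#'   `stop()`.
#' @export
mock_server <- function(kind = c("pages", "eutils", "files", "echo", "http"),
                        args = list(), port = NULL, startup_timeout = 20) {
  kind <- match.arg(kind)
  if (is.null(port)) port <- httpuv::randomPort()
  px <- callr::r_bg(
    function(kind, args, port) {
      if (kind == "http") {
        rargs <- args$registry_args
        if (is.null(rargs)) rargs <- list()
        registry <- do.call(
          getExportedValue("biocrumbs", args$registry_fn), rargs
        )
        biocrumbs::serve_http(registry, port = port)
      } else {
        fn <- getExportedValue("biocrumbs", paste0("run_mock_", kind))
        do.call(fn, c(list(port = port), args))
      }
    },
    args = list(kind = kind, args = args, port = port),
    supervise = TRUE
  )
  base_url <- sprintf("http://127.0.0.1:%d", port)
  t0 <- Sys.time()
  ready <- FALSE
  while (as.numeric(Sys.time() - t0, units = "secs") < startup_timeout) {
    if (!px$is_alive()) break
    ok <- tryCatch({
      res <- curl::curl_fetch_memory(
        paste0(base_url, "/__ping"),
        handle = curl::new_handle(timeout = 2)
      )
      res$status_code == 200
    }, error = function(e) FALSE)
    if (isTRUE(ok)) {
      ready <- TRUE
      break
    }
    Sys.sleep(0.1)
  }
  if (!ready) {
    err <- tryCatch(px$read_all_error(), error = function(e) "")
    px$kill()
    stop(sprintf("mock %s server failed to start on port %d: %s",
                 kind, port, err))
  }
  structure(
    list(
      base_url = base_url, port = port, process = px,
      stop = function() invisible(if (px$is_alive()) px$kill())
    ),
    class = "mock_server"
  )
}
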