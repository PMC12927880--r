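# Capability negotiation, frame handling, crash resistance, the HTTP mode
# (routes, CORS, OpenAPI, SSE, health), and stdio/HTTP transport
# equivalence against a fixed mock backend.

eutils_srv <- start_server("eutils")
cfg <- eutils_config(base_url = eutils_srv$base_url, min_interval = 0.01,
                     download_dir = file.path(tempdir(), "transport-dl"))
registry <- geo_registry(cfg)

stdio_roundtrip <- function(reg, frames) {
  inp <- textConnection(frames)
  out <- textConnection("captured", "w", local = TRUE)
  on.exit({ close(inp); close(out) })
  serve_stdio(reg, inp, out)
  lapply(textConnectionValue(out), parse_json)
}

rpc <- function(id, method, params = NULL) {
  msg <- list(jsonrpc = "2.0", id = id, method = method)
  if (!is.null(params)) msg$params <- params
  canonical_json(msg)
}

test_that("initialization advertises capabilities before any tool call", {
  res <- stdio_roundtrip(registry, rpc(1, "initialize", list()))
  expect_identical(res[[1]]$result$protocolVersion, "2024-11-05")
  expect_true("tools" %in% names(res[[1]]$result$capabilities))
  expect_identical(res[[1]]$result$serverInfo$name, "geo-mcp")
})

test_that("tools/list returns 8 descriptors for GEO and 3 for breadcrumbs", {
  res <- stdio_roundtrip(registry, rpc(1, "tools/list"))
  tools <- res[[1]]$result$tools
  expect_length(tools, 8)
  expect_identical(tools[[1]]$name, "search_geo")
  expect_true(all(c("inputSchema", "description", "concepts") %in%
                    names(tools[[1]])))
  bres <- stdio_roundtrip(breadcrumbs_registry(), rpc(1, "tools/list"))
  bnames <- vapply(bres[[1]]$result$tools, function(t) t$name, character(1))
  expect_identical(bnames,
                   c("discover_service", "execute_endpoint", "list_endpoints"))
})

test_that("tools/call dispatches searches over stdio", {
  res <- stdio_roundtrip(registry, rpc(
    7, "tools/call",
    list(name = "search_geo",
         arguments = list(term = "microglia depletion", retmax = 10))
  ))
  r <- res[[1]]$result
  expect_false(r$isError)
  payload <- parse_json(r$content[[1]]$json)
  expect_identical(unlist(payload$uids)[1:2], c("200299005", "200279739"))
})

test_that("unknown tools and methods get structured protocol errors", {
  res <- stdio_roundtrip(registry, c(
    rpc(1, "tools/call", list(name = "no_such_tool", arguments = list())),
    rpc(2, "bogus/method")
  ))
  expect_identical(res[[1]]$error$code, -32602L)
  expect_match(res[[1]]$error$message, "no_such_tool")
  expect_identical(res[[2]]$error$code, -32601L)
})

test_that("malformed frames are answered, not fatal, and the server keeps serving", {
  corpus <- c(
    "not json at all",
    "{\"jsonrpc\":\"2.0\",\"id\":1}",          # no method
    "{}",
    "[1,2,3]",
    "{\"jsonrpc\":\"2.0\",\"id\":2,\"method\":5}",
    "{\"jsonrpc\":\"2.0\",\"id\":3,\"method\":\"tools/call\",\"params\":{}}",
    rpc(4, "ping")                             # still answered after the junk
  )
  res <- stdio_roundtrip(registry, corpus)
  expect_length(res, 7)
  expect_identical(res[[1]]$error$code, -32700L)
  expect_identical(res[[2]]$error$code, -32600L)
  expect_identical(res[[6]]$error$code, -32602L)
  expect_true(!is.null(res[[7]]$result))
})

test_that("notifications produce no response frames", {
  frames <- c(
    "{\"jsonrpc\":\"2.0\",\"method\":\"notifications/initialized\"}",
    rpc(1, "ping")
  )
  res <- stdio_roundtrip(registry, frames)
  expect_length(res, 1)
})

test_that("handler exceptions become tool-error responses, not crashes", {
  broken <- mcp_registry("broken", "0.0.1", tools = list(
    boom = list(
      descriptor = tool_descriptor("boom", "always fails",
                                   list(type = "object"), list(type = "object"),
                                   list("test")),
      handler = function(args) stop("internal explosion")
    )
  ))
  res <- stdio_roundtrip(broken, rpc(1, "tools/call",
                                     list(name = "boom", arguments = list())))
  r <- res[[1]]$result
  expect_true(r$isError)
  expect_match(r$content[[1]]$text, "internal explosion")
})

# -- HTTP mode -----------------------------------------------------------

http_srv <- start_server("http", args = list(
  registry_fn = "geo_registry", registry_args = list(cfg = cfg)
))

http_get <- function(path) {
  res <- curl::curl_fetch_memory(paste0(http_srv$base_url, path))
  list(status = res$status_code,
       headers = curl::parse_headers_list(res$headers),
       text = rawToChar(res$content))
}

http_post <- function(path, body) {
  h <- curl::new_handle(copypostfields = canonical_json(body))
  curl::handle_setheaders(h, "Content-Type" = "application/json")
  res <- curl::curl_fetch_memory(paste0(http_srv$base_url, path), handle = h)
  list(status = res$status_code, text = rawToChar(res$content))
}

test_that("the OpenAPI document lists one operation per tool", {
  r <- http_get("/openapi.json")
  expect_identical(r$status, 200L)
  doc <- parse_json(r$text)
  expect_identical(doc$openapi, "3.0.3")
  expect_length(doc$paths, 8)
  expect_true("/tools/search_geo" %in% names(doc$paths))
  op <- doc$paths[["/tools/search_geo"]]$post
  expect_identical(op$operationId, "search_geo")
  expect_identical(
    op$requestBody$content[["application/json"]]$schema$required,
    list("term")
  )
})

test_that("cross-origin headers are present on preflight and normal responses", {
  pre <- curl::curl_fetch_memory(
    paste0(http_srv$base_url, "/tools/search_geo"),
    handle = curl::new_handle(customrequest = "OPTIONS")
  )
  hdr <- curl::parse_headers_list(pre$headers)
  expect_identical(hdr[["access-control-allow-origin"]], "*")
  expect_match(hdr[["access-control-allow-methods"]], "POST")
  normal <- http_get("/health")
  expect_identical(normal$headers[["access-control-allow-origin"]], "*")
})

test_that("the health probe reports liveness and registry size", {
  r <- http_get("/health")
  h <- parse_json(r$text)
  expect_identical(h$status, "ok")
  expect_identical(h$tools, 8L)
  expect_false(h$config_fallback)
})

test_that("health reflects config fallbacks and degraded registries", {
  warn_cfg <- cfg
  warn_cfg$warnings <- "config file not found; using defaults"
  reg <- mcp_registry("geo-mcp", "0.1.0",
                      tools = registry$tools,
                      config_warnings = warn_cfg$warnings)
  h <- health(reg)
  expect_identical(h$status, "ok")
  expect_true(h$config_fallback)
  expect_identical(health(NULL)$status, "degraded")
})

test_that("unknown tool routes answer structured 404s", {
  r <- http_post("/tools/no_such_tool", list(term = "x"))
  expect_identical(r$status, 404L)
  expect_match(parse_json(r$text)$error, "no_such_tool")
  bad <- curl::curl_fetch_memory(
    paste0(http_srv$base_url, "/tools/search_geo"),
    handle = {
      h <- curl::new_handle(copypostfields = "{not json")
      curl::handle_setheaders(h, "Content-Type" = "application/json")
      h
    }
  )
  expect_identical(bad$status_code, 400L)
})

test_that("stdio and HTTP return payload-identical results for every search tool", {
  for (tool in c("search_geo", "search_geo_profiles", "search_geo_series")) {
    for (term in c("microglia depletion", "microglia PLX3397 mouse")) {
      sres <- stdio_roundtrip(registry, rpc(
        1, "tools/call",
        list(name = tool, arguments = list(term = term, retmax = 10))
      ))[[1]]$result
      hres <- parse_json(http_post(paste0("/tools/", tool),
                                   list(term = term, retmax = 10))$text)
      expect_identical(hres$content[[1]]$json, sres$content[[1]]$json,
                       label = sprintf("%s / %s", tool, term))
      expect_identical(hres$isError, sres$isError)
    }
  }
})

test_that("both transports advertise identical tool descriptors", {
  sres <- stdio_roundtrip(registry, rpc(1, "tools/list"))[[1]]$result$tools
  hres <- parse_json(http_get("/tools")$text)$tools
  expect_identical(hres, sres)
})

test_that("a malformed-request corpus leaves the HTTP server responsive", {
  for (path in c("/tools/search_geo", "/nope", "/tools/", "/events")) {
    h <- curl::new_handle(copypostfields = "garbage{{{")
    tryCatch(curl::curl_fetch_memory(paste0(http_srv$base_url, path), handle = h),
             error = function(e) NULL)
  }
  r <- http_get("/health")
  expect_identical(parse_json(r$text)$status, "ok")
})

test_that("the event stream emits progress then a terminal event for a download", {
  set.seed(9)
  content <- paste(rep("z", 30000), collapse = "")
  slow_files <- start_server("files", args = list(
    catalog = list("GSE500_family.soft.gz" = list(content = content, delay = 1.2))
  ))
  tpl <- paste0(slow_files$base_url, "/files/{acc}_family.soft.gz")
  sse_cfg <- eutils_config(
    base_url = eutils_srv$base_url, min_interval = 0.01,
    download_dir = file.path(tempdir(), "sse-dl"),
    soft_url_templates = c(series = tpl, samples = tpl,
                           platforms = tpl, datasets = tpl)
  )
  sse_srv <- start_server("http", args = list(
    registry_fn = "geo_registry", registry_args = list(cfg = sse_cfg)
  ))
  h <- curl::new_handle(
    copypostfields = canonical_json(list(accession = "GSE500", wait = FALSE)))
  curl::handle_setheaders(h, "Content-Type" = "application/json")
  submit <- parse_json(rawToChar(curl::curl_fetch_memory(
    paste0(sse_srv$base_url, "/tools/download_geo_data"), handle = h)$content))
  job_id <- parse_json(submit$content[[1]]$json)$job_id
  ev <- curl::curl_fetch_memory(
    paste0(sse_srv$base_url, "/events?job_id=", job_id))
  expect_match(curl::parse_headers_list(ev$headers)[["content-type"]],
               "text/event-stream")
  txt <- rawToChar(ev$content)
  progress_n <- length(gregexpr("event: progress", txt, fixed = TRUE)[[1]])
  expect_gte(progress_n, 1)
  expect_match(txt, "event: done")
  last <- regmatches(txt, gregexpr("data: \\{[^\n]*\\}", txt))[[1]]
  final <- parse_json(sub("^data: ", "", last[length(last)]))
  expect_identical(final$state, "completed")
  expect_identical(final$bytes_done, 30000L)
})
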