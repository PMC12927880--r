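# Shared fixtures and small generators used across the suite. Mock servers
# are started per test file and torn down via withr::defer.

start_server <- function(kind, args = list()) {
  srv <- mock_server(kind, args = args)
  withr::defer(srv$stop(), envir = teardown_env())
  srv
}

# Generator for random-but-valid breadcrumb documents; strings are drawn
# to include the characters that historically corrupt HTML-comment
# payloads (comment terminators, nested comment openers, quotes,
# backslashes, newlines, unicode).
random_document <- function() {
  nasty <- c(
    "plain text", "has --> terminator", "<!-- nested opener",
    "quote \" and backslash \\", "multi\nline", "ends with --",
    "--> at start", "unicode é世", "<!--->", "a --> b --> c"
  )
  rs <- function() sample(nasty, 1)
  n_ep <- sample(1:3, 1)
  eps <- lapply(seq_len(n_ep), function(i) {
    n_par <- sample(0:3, 1)
    params <- lapply(seq_len(n_par), function(j) {
      param_spec(
        name = paste0("p", j),
        value_type = sample(c("string", "integer", "number", "boolean", "array"), 1),
        required = sample(c(TRUE, FALSE), 1),
        description = if (sample(c(TRUE, FALSE), 1)) rs() else NULL
      )
    })
    endpoint_spec(
      method = sample(c("GET", "POST", "PUT", "DELETE"), 1),
      url = sample(c("/api/x", "https://svc.example.org/api/y"), 1),
      concept = sample(c("search_data", "download_file", "map_identifiers"), 1),
      params = params,
      concept_iris = if (sample(c(TRUE, FALSE), 1)) c("edam:operation_0224") else NULL,
      example = if (sample(c(TRUE, FALSE), 1)) rs() else NULL
    )
  })
  has_mcp <- sample(c(TRUE, FALSE), 1)
  breadcrumb_document(
    service_name = rs(), service_version = "1.0.3",
    mcp_available = has_mcp,
    redirect_url = if (has_mcp) "https://svc.example.org/mcp" else NULL,
    endpoints = eps
  )
}

# Random SOFT documents with known ground truth for round-trip checks.
random_soft_document <- function() {
  n_ent <- sample(1:4, 1)
  entities <- lapply(seq_len(n_ent), function(i) {
    type <- sample(c("SERIES", "SAMPLE", "PLATFORM"), 1)
    id <- sprintf("%s%d", substr(type, 1, 3), sample(1000:9999, 1))
    n_attr <- sample(1:4, 1)
    attrs <- stats::setNames(
      lapply(seq_len(n_attr), function(j) paste("value", sample(100, 1))),
      paste0(tolower(type), "_attr", seq_len(n_attr))
    )
    tab <- NULL
    cols <- character(0)
    if (sample(c(TRUE, FALSE), 1)) {
      cols <- c("ID_REF", "VALUE")
      tab <- data.frame(
        ID_REF = sprintf("probe%d", 1:3),
        VALUE = as.character(round(stats::runif(3), 3)),
        stringsAsFactors = FALSE
      )
    }
    list(entity_type = type, entity_id = id, attributes = attrs,
         columns = cols, table = tab)
  })
  structure(list(entities = entities), class = "soft_document")
}

# Independent reference canonicalization for path checks: repeated textual
# reduction of "." and ".." segments, distinct from the stack-based
# implementation under test.
reference_normalize <- function(path) {
  p <- gsub("/+", "/", path)
  repeat {
    q <- sub("/\\./", "/", p)
    if (identical(q, p)) break
    p <- q
  }
  p <- sub("/\\.$", "/", p)
  repeat {
    q <- sub("/[^/.][^/]*/\\.\\.(/|$)", "/", p)
    q <- sub("^/\\.\\.(/|$)", "/", q)
    if (identical(q, p)) break
    p <- q
  }
  sub("(.)/$", "\\1", p)
}

# Brute-force scheduler: grants request slots one at a time on a fine time
# grid, subject to the spacing and (optionally) window-ceiling rules.
brute_force_schedule <- function(arrivals, keyed, min_interval = 0.1,
                                 ceiling = 10, grid = 0.005) {
  grants <- numeric(0)
  for (a in arrivals) {
    t <- a
    if (length(grants) > 0) t <- max(t, max(grants) + min_interval)
    t <- round(t / grid) * grid
    repeat {
      ok <- TRUE
      if (length(grants) > 0 && t < max(grants) + min_interval - 1e-9) ok <- FALSE
      if (ok && keyed) {
        inwin <- sum(grants > t - 1 + 1e-9)
        if (inwin >= ceiling) ok <- FALSE
      }
      if (ok) break
      t <- t + grid
    }
    grants <- c(grants, t)
  }
  grants
}
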