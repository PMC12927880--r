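# Rate-limited client for the NCBI E-utilities endpoints used for GEO
# discovery: ESearch (UID lists for a query term) and ESummary (per-UID
# document summaries), plus configuration loading and the rate-limiter's
# pure scheduling function.

EUTILS_DBS <- c("gds", "geoprofiles")

#' E-utilities client configuration
#'
#' Builds a configuration with the package defaults. The upstream service
#' requires an email with every request; an optional API key raises the
#' allowed request rate. The default inter-request delay is 0.1 s, with a
#' 10 requests/second ceiling when an API key is present; the unkeyed
#' interval is operator-configurable upward.
#'
#' @param email Contact email sent with every request.
#' @param api_key Optional API key; when present the keyed per-second
#'   ceiling applies.
#' @param base_url E-utilities base URL (overridable so the scripted mock
#'   emulator can stand in for the live service).
#' @param min_interval Minimum seconds between consecutive requests
#'   (default 0.1).
#' @param rps_ceiling_with_key Maximum granted requests in any 1-second
#'   window when an API key is configured (default 10).
#' @param download_dir Root directory for downloaded artifacts.
#' @param timeouts Named deadlines in seconds: `request` (per E-utilities
#'   call, default 30) and `download` (per archive transfer, default 300).
#' @param soft_url_templates Named character vector (series, samples,
#'   platforms, datasets) of URL templates for SOFT archives; `{acc}` is
#'   replaced by the accession and `{stub}` by the accession with its last
#'   three digits replaced by `nnn` (the upstream directory layout).
#' @param warnings Character vector of configuration warnings (filled by
#'   [load_eutils_config()] when falling back to defaults).
#' @return An `eutils_config` object.
#' @export
eutils_config <- function(email = "anonymous@example.org",
                          api_key = NULL,
                          base_url = "https://eutils.ncbi.nlm.nih.gov/entrez/eutils",
                          min_interval = 0.1,
                          rps_ceiling_with_key = 10,
                          download_dir = file.path("~", ".geo-mcp", "downloads"),
                          timeouts = list(request = 30, download = 300),
                          soft_url_templates = NULL,
                          warnings = character(0)) {
  stopifnot(min_interval > 0, rps_ceiling_with_key > 0)
  defaults_t <- list(request = 30, download = 300)
  for (nm in names(defaults_t)) {
    if (is.null(timeouts[[nm]])) timeouts[[nm]] <- defaults_t[[nm]]
  }
  if (is.null(soft_url_templates)) {
    base <- "https://ftp.ncbi.nlm.nih.gov/geo"
    soft_url_templates <- c(
      series    = paste0(base, "/series/{stub}/{acc}/soft/{acc}_family.soft.gz"),
      samples   = paste0(base, "/samples/{stub}/{acc}/soft/{acc}_family.soft.gz"),
      platforms = paste0(base, "/platforms/{stub}/{acc}/soft/{acc}_family.soft.gz"),
      datasets  = paste0(base, "/datasets/{stub}/{acc}/soft/{acc}_full.soft.gz")
    )
  }
  structure(
    list(
      email = email, api_key = api_key, base_url = base_url,
      min_interval = min_interval,
      rps_ceiling_with_key = rps_ceiling_with_key,
      download_dir = download_dir, timeouts = timeouts,
      soft_url_templates = soft_url_templates,
      warnings = warnings
    ),
    class = "eutils_config"
  )
}

#' Load configuration from a JSON file
#'
#' Reads the user configuration (conventionally at
#' `~/.geo-mcp/config.json`). A missing file, or missing individual fields,
#' fall back to the package defaults with an emitted warning — startup is
#' never aborted. Only a file that exists but cannot be decoded as JSON at
#' all signals `eutils_config_error`.
#'
#' @param path Path to the JSON configuration file.
#' @return An [eutils_config()] whose `warnings` field records any
#'   fallbacks that were applied.
#' @export
load_eutils_config <- function(path = file.path("~", ".geo-mcp", "config.json")) {
  path <- path.expand(path)
  if (!file.exists(path)) {
    w <- sprintf("config file %s not found; using defaults", path)
    warning(w, call. = FALSE)
    return(eutils_config(warnings = w))
  }
  raw <- tryCatch(
    parse_json(paste(readLines(path, warn = FALSE), collapse = "\n")),
    error = function(e) {
      stop_config(sprintf("config file %s is not decodable JSON: %s",
                          path, conditionMessage(e)))
    }
  )
  if (!is.list(raw)) stop_config(sprintf("config file %s is not a JSON object", path))
  warn <- character(0)
  take <- function(name, check, default) {
    v <- raw[[name]]
    if (is.null(v)) return(default)
    if (!check(v)) {
      warn <<- c(warn, sprintf("config field '%s' invalid; using default", name))
      return(default)
    }
    v
  }
  d <- eutils_config()
  cfg <- eutils_config(
    email = take("email", is_nonempty_string, d$email),
    api_key = take("api_key", is_nonempty_string, NULL),
    base_url = take("base_url", is_nonempty_string, d$base_url),
    min_interval = take("min_interval", function(x) is.numeric(x) && x > 0,
                        d$min_interval),
    rps_ceiling_with_key = take("rps_ceiling_with_key",
                                function(x) is.numeric(x) && x > 0,
                                d$rps_ceiling_with_key),
    download_dir = take("download_dir", is_nonempty_string, d$download_dir),
    timeouts = take("timeouts", is.list, d$timeouts)
  )
  missing <- setdiff(c("email"), names(raw))
  if (length(missing) > 0L) {
    warn <- c(warn, sprintf("config field '%s' missing; using default", missing))
  }
  cfg$warnings <- warn
  if (length(warn) > 0L) warning(paste(warn, collapse = "; "), call. = FALSE)
  cfg
}

# -- rate limiter --------------------------------------------------------

#' Create an empty rate-limiter state
#'
#' @return A `rate_limiter_state`: no previous grant, empty 1-second
#'   window history.
#' @export
limiter_state <- function() {
  structure(
    list(last = -Inf, recent = numeric(0)),
    class = "rate_limiter_state"
  )
}

#' Acquire a request slot (pure scheduling function)
#'
#' Computes the smallest non-negative wait such that the granted time is at
#' least `min_interval` after the previous grant and — when an API key is
#' in use — at most `ceiling` grants fall in any sliding 1-second window.
#' No clock is read: the caller supplies `now`, which makes the scheduler
#' testable on a simulated clock.
#'
#' @param state A [limiter_state()] (carries the previous grant time and
#'   the grant times still inside the trailing 1-second window).
#' @param now Current monotonic time in seconds. Under a burst `now` may
#'   trail the last granted slot; grants are then scheduled into the
#'   future and the returned wait covers the difference.
#' @param keyed Is an API key configured (activates the window ceiling)?
#' @param min_interval Minimum spacing between grants in seconds.
#' @param ceiling Maximum grants per sliding 1-second window when keyed.
#' @return `list(wait = <seconds>, state = <updated state>)`; the granted
#'   time is `now + wait`.
#' @export
acquire_slot <- function(state, now, keyed = FALSE,
                         min_interval = 0.1, ceiling = 10) {
  # under a burst the caller's clock may trail the last *granted* slot
  # (grants are scheduled into the future); only request order matters
  grant <- max(now, state$last + min_interval)
  if (isTRUE(keyed)) {
    repeat {
      window <- state$recent[state$recent > grant - 1]
      if (length(window) < ceiling) break
      # earliest time at which the oldest of the newest `ceiling` grants
      # has left the trailing window
      kick <- sort(window, decreasing = TRUE)[ceiling]
      grant2 <- max(grant, kick + 1)
      if (grant2 <= grant) break
      grant <- grant2
    }
  }
  recent <- c(state$recent[state$recent > grant - 1], grant)
  list(
    wait = grant - now,
    state = structure(list(last = grant, recent = recent),
                      class = "rate_limiter_state")
  )
}

# Shared limiter used by the live client functions: one state per
# (base_url) kept in the package namespace, advanced against the real
# monotonic clock.
.limiters <- new.env(parent = emptyenv())

wait_for_slot <- function(cfg, sleep_fn = Sys.sleep) {
  key <- cfg$base_url
  st <- get0(key, envir = .limiters, ifnotfound = limiter_state())
  res <- acquire_slot(
    st, monotonic_now(),
    keyed = !is.null(cfg$api_key),
    min_interval = cfg$min_interval,
    ceiling = cfg$rps_ceiling_with_key
  )
  assign(key, res$state, envir = .limiters)
  if (res$wait > 0) sleep_fn(res$wait)
  invisible(res$wait)
}

# -- request construction ------------------------------------------------

#' Build an ESearch request URL
#'
#' Deterministic, fully percent-encoded URL construction: `db`, `term`,
#' `retmax`, `retstart`, `retmode=json`, the mandatory `email`, and
#' `api_key` iff configured.
#'
#' @param term Query string.
#' @param db Target database: `"gds"` or `"geoprofiles"`.
#' @param retmax Maximum number of UIDs to return (>= 1).
#' @param retstart Offset into the result list (>= 0).
#' @param cfg An [eutils_config()].
#' @return The request URL as a string.
#' @export
build_esearch_url <- function(term, db = "gds", retmax = 20, retstart = 0,
                              cfg = eutils_config()) {
  check_esearch_request(term, db, retmax, retstart)
  params <- list(
    db = db, term = term, retmax = retmax, retstart = retstart,
    retmode = "json", email = cfg$email
  )
  if (!is.null(cfg$api_key)) params$api_key <- cfg$api_key
  append_query(paste0(cfg$base_url, "/esearch.fcgi"), params)
}

build_esummary_url <- function(uids, db, cfg, retmode = "json") {
  params <- list(
    db = db, id = paste(uids, collapse = ","), retmode = retmode,
    email = cfg$email
  )
  if (!is.null(cfg$api_key)) params$api_key <- cfg$api_key
  append_query(paste0(cfg$base_url, "/esummary.fcgi"), params)
}

check_esearch_request <- function(term, db, retmax, retstart) {
  if (!is_nonempty_string(term)) {
    stop(bc_error("eutils_request_error", "term must be a non-empty string"))
  }
  if (!is_string(db) || !(db %in% EUTILS_DBS)) {
    stop(bc_error("eutils_request_error",
                  sprintf("db must be one of: %s", paste(EUTILS_DBS, collapse = ", "))))
  }
  if (!is_count(retmax) || retmax < 1) {
    stop(bc_error("eutils_request_error", "retmax must be a positive integer"))
  }
  if (!is_count(retstart)) {
    stop(bc_error("eutils_request_error", "retstart must be a non-negative integer"))
  }
  invisible(TRUE)
}

# One GET with the client retry policy: one retry on 5xx or connection
# error (each attempt is rate-limited), then eutils_upstream_error.
eutils_get <- function(url, cfg, sleep_fn = Sys.sleep) {
  for (attempt in 1:2) {
    wait_for_slot(cfg, sleep_fn = sleep_fn)
    h <- curl::new_handle(timeout = cfg$timeouts$request)
    res <- tryCatch(curl::curl_fetch_memory(url, handle = h), error = function(e) e)
    failed <- inherits(res, "error") || res$status_code >= 500
    if (!failed) {
      if (res$status_code >= 400) {
        stop_upstream(sprintf("E-utilities answered HTTP %d", res$status_code),
                      status = res$status_code)
      }
      return(rawToChar(res$content))
    }
    if (attempt == 2L) {
      if (inherits(res, "error")) {
        stop_upstream(sprintf("E-utilities request failed after retry: %s",
                              conditionMessage(res)))
      }
      stop_upstream(sprintf("E-utilities answered HTTP %d after retry",
                            res$status_code), status = res$status_code)
    }
  }
}

# -- response parsing ----------------------------------------------------

parse_esearch_json <- function(txt) {
  body <- parse_json(txt)
  r <- body$esearchresult
  if (is.null(r)) stop("no esearchresult")
  uids <- vapply(r$idlist %||% list(), as.character, character(1))
  list(
    count = as.integer(r$count),
    uids = uids,
    translated_query = if (!is.null(r$querytranslation)) as.character(r$querytranslation) else NULL
  )
}

parse_esearch_xml <- function(txt) {
  x <- xml2::read_xml(txt)
  list(
    count = as.integer(xml2::xml_text(xml2::xml_find_first(x, "//Count"))),
    uids = xml2::xml_text(xml2::xml_find_all(x, "//IdList/Id")),
    translated_query = {
      qt <- xml2::xml_find_first(x, "//QueryTranslation")
      if (length(qt) == 0) NULL else xml2::xml_text(qt)
    }
  )
}

#' Search a GEO database via ESearch
#'
#' Issues one rate-limited GET and parses the UID list. An empty UID list
#' is a normal result, not an error — LLM clients are expected to refine
#' their terms and search again. Responses are parsed as JSON first, with
#' an XML fallback on parse failure.
#'
#' @inheritParams build_esearch_url
#' @return An `esearch_result`: `count` (total matches), `uids` (character
#'   vector, length <= `retmax`, possibly empty), `translated_query`.
#' @export
esearch <- function(term, db = "gds", retmax = 20, retstart = 0,
                    cfg = eutils_config()) {
  check_esearch_request(term, db, retmax, retstart)
  url <- build_esearch_url(term, db, retmax, retstart, cfg)
  txt <- eutils_get(url, cfg)
  parsed <- tryCatch(parse_esearch_json(txt), error = function(e) {
    tryCatch(parse_esearch_xml(txt), error = function(e2) {
      stop_parse(sprintf("ESearch response unparseable as JSON or XML: %s",
                         conditionMessage(e2)))
    })
  })
  if (length(parsed$uids) > retmax) parsed$uids <- parsed$uids[seq_len(retmax)]
  structure(
    list(
      count = parsed$count, uids = parsed$uids,
      translated_query = parsed$translated_query,
      term = term, db = db
    ),
    class = "esearch_result"
  )
}

GEO_PREFIXES <- c(GSE = "series", GSM = "samples", GPL = "platforms", GDS = "datasets")

accession_type <- function(acc) {
  acc <- trimws(acc)
  pfx <- substr(acc, 1, 3)
  hit <- pfx %in% names(GEO_PREFIXES) & grepl("^[A-Z]{3}[0-9]+$", acc)
  ifelse(hit, GEO_PREFIXES[pfx], "other")
}

new_esummary_record <- function(uid, rec) {
  acc <- rec$accession %||% rec$acc %||% ""
  structure(
    list(
      uid = as.character(uid),
      accession = as.character(acc),
      accession_type = unname(accession_type(as.character(acc))),
      title = as.character(rec$title %||% ""),
      summary = as.character(rec$summary %||% ""),
      organism = if (!is.null(rec$taxon)) as.character(rec$taxon) else NULL,
      entry_type = if (!is.null(rec$entrytype)) as.character(rec$entrytype) else NULL
    ),
    class = "esummary_record"
  )
}

parse_esummary_json <- function(txt, uids) {
  body <- parse_json(txt)
  res <- body$result
  if (is.null(res)) stop("no result object")
  records <- list()
  unresolved <- character(0)
  for (u in uids) {
    rec <- res[[as.character(u)]]
    if (is.null(rec) || !is.null(rec$error)) {
      unresolved <- c(unresolved, as.character(u))
    } else {
      records[[length(records) + 1L]] <- new_esummary_record(u, rec)
    }
  }
  list(records = records, unresolved = unresolved)
}

#' Retrieve record metadata via ESummary
#'
#' One batched, rate-limited request for the given UIDs. Order is
#' preserved; UIDs the service cannot resolve are reported in the
#' `unresolved` side list rather than dropped silently.
#'
#' @param uids Non-empty character/numeric vector of UIDs.
#' @param db Target database (`"gds"` or `"geoprofiles"`).
#' @param cfg An [eutils_config()].
#' @return An `esummary_result`: `records` (list of `esummary_record`, in
#'   input order) and `unresolved` (character vector).
#' @export
esummary <- function(uids, db = "gds", cfg = eutils_config()) {
  if (length(uids) == 0L) {
    stop(bc_error("eutils_request_error", "uids must be non-empty"))
  }
  if (!is_string(db) || !(db %in% EUTILS_DBS)) {
    stop(bc_error("eutils_request_error",
                  sprintf("db must be one of: %s", paste(EUTILS_DBS, collapse = ", "))))
  }
  uids <- as.character(uids)
  url <- build_esummary_url(uids, db, cfg)
  txt <- eutils_get(url, cfg)
  parsed <- tryCatch(parse_esummary_json(txt, uids), error = function(e) {
    stop_parse(sprintf("ESummary response unparseable: %s", conditionMessage(e)))
  })
  structure(
    list(records = parsed$records, unresolved = parsed$unresolved),
    class = "esummary_result"
  )
}
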