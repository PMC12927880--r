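# Configuration loading, the rate limiter's scheduling function (against a
# brute-force oracle on a simulated clock), URL construction, and the
# ESearch/ESummary client against the scripted emulator.

eutils <- start_server("eutils")

mock_cfg <- function(...) {
  eutils_config(base_url = eutils$base_url, min_interval = 0.01, ...)
}

test_that("absent config files fall back to full defaults with a warning", {
  path <- file.path(tempdir(), "no-such-dir", "config.json")
  expect_warning(cfg <- load_eutils_config(path), "not found")
  expect_s3_class(cfg, "eutils_config")
  expect_identical(cfg$min_interval, 0.1)
  expect_identical(cfg$rps_ceiling_with_key, 10)
  expect_null(cfg$api_key)
  expect_true(length(cfg$warnings) > 0)
})

test_that("partial config files keep defaults for unset fields", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"email": "user@lab.org"}', path)
  cfg <- load_eutils_config(path)
  expect_identical(cfg$email, "user@lab.org")
  expect_identical(cfg$min_interval, 0.1)
  expect_identical(cfg$timeouts$request, 30)
  expect_identical(cfg$timeouts$download, 300)
})

test_that("an api_key in the config activates the keyed ceiling", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"email": "user@lab.org", "api_key": "K123"}', path)
  cfg <- load_eutils_config(path)
  expect_identical(cfg$api_key, "K123")
  expect_identical(cfg$rps_ceiling_with_key, 10)
})

test_that("invalid field values fall back individually with warnings", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"email": "user@lab.org", "min_interval": -5}', path)
  expect_warning(cfg <- load_eutils_config(path), "min_interval")
  expect_identical(cfg$min_interval, 0.1)
  expect_identical(cfg$email, "user@lab.org")
})

test_that("a file that is not JSON at all is a config error", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines("not json {", path)
  expect_error(load_eutils_config(path), class = "eutils_config_error")
})

test_that("two requests at the same instant are spaced by the 0.1 s delay", {
  st <- limiter_state()
  a <- acquire_slot(st, now = 0)
  expect_identical(a$wait, 0)
  b <- acquire_slot(a$state, now = 0)
  expect_equal(b$wait, 0.1)
})

test_that("a single request with empty history waits nothing", {
  a <- acquire_slot(limiter_state(), now = 123.4)
  expect_identical(a$wait, 0)
})

test_that("grant spacing >= min_interval holds over random request traces", {
  set.seed(11)
  for (rep in 1:10) {
    st <- limiter_state()
    now <- 0
    grants <- numeric(0)
    for (i in 1:30) {
      now <- now + stats::runif(1, 0, 0.15)
      res <- acquire_slot(st, now, keyed = (rep %% 2 == 0))
      grants <- c(grants, now + res$wait)
      st <- res$state
      now <- now + res$wait # caller sleeps the returned wait
    }
    expect_true(all(diff(grants) >= 0.1 - 1e-9))
  }
})

test_that("a keyed burst satisfies both constraints and matches the brute-force scheduler", {
  st <- limiter_state()
  grants <- numeric(0)
  for (i in 1:25) {
    res <- acquire_slot(st, now = 0, keyed = TRUE)
    grants <- c(grants, res$wait)
    st <- res$state
  }
  # spacing
  expect_true(all(diff(grants) >= 0.1 - 1e-9))
  # ceiling: brute-force scan of every trailing half-open 1-second window
  for (t in grants) {
    expect_lte(sum(grants > t - 1 + 1e-9 & grants <= t + 1e-9), 10)
  }
  oracle <- brute_force_schedule(rep(0, 25), keyed = TRUE)
  expect_equal(grants, oracle, tolerance = 0.02)
})

test_that("the window ceiling binds when spacing alone would exceed it", {
  # 0.02 s spacing admits 50/s; a ceiling of 5 must stretch the schedule
  st <- limiter_state()
  grants <- numeric(0)
  for (i in 1:12) {
    res <- acquire_slot(st, now = 0, keyed = TRUE,
                        min_interval = 0.02, ceiling = 5)
    grants <- c(grants, res$wait)
    st <- res$state
  }
  for (t in grants) {
    expect_lte(sum(grants > t - 1 + 1e-9 & grants <= t + 1e-9), 5)
  }
  oracle <- brute_force_schedule(rep(0, 12), keyed = TRUE,
                                 min_interval = 0.02, ceiling = 5)
  expect_equal(grants, oracle, tolerance = 0.02)
  # the ceiling actually bit: the burst takes > 1 s, pure spacing would not
  expect_gt(max(grants), 1)
  expect_lt(12 * 0.02, 1)
})

test_that("an unkeyed burst matches the brute-force scheduler", {
  st <- limiter_state()
  grants <- numeric(0)
  for (i in 1:15) {
    res <- acquire_slot(st, now = 0, keyed = FALSE)
    grants <- c(grants, res$wait)
    st <- res$state
  }
  oracle <- brute_force_schedule(rep(0, 15), keyed = FALSE)
  expect_equal(grants, oracle, tolerance = 0.02)
})

test_that("esearch URLs are deterministic, encoded, and carry identity", {
  cfg <- eutils_config(email = "me@lab.org")
  url <- build_esearch_url("microglia depletion mouse", db = "gds",
                           retmax = 5, cfg = cfg)
  expect_false(grepl(" ", url))
  expect_match(url, "term=microglia%20depletion%20mouse")
  expect_match(url, "db=gds")
  expect_match(url, "retmax=5")
  expect_match(url, "email=me%40lab.org")
  expect_false(grepl("api_key", url))
  keyed <- eutils_config(email = "me@lab.org", api_key = "K1")
  expect_match(build_esearch_url("x", cfg = keyed), "api_key=K1")
  prof <- build_esearch_url("x", db = "geoprofiles", cfg = keyed)
  expect_match(prof, "db=geoprofiles")
})

test_that("empty-result searches return empty UID lists, not errors", {
  r <- esearch("microglia depletion mouse", retmax = 5, cfg = mock_cfg())
  expect_s3_class(r, "esearch_result")
  expect_identical(r$count, 0L)
  expect_length(r$uids, 0)
})

test_that("the scripted broad term returns the transcript UID prefix", {
  r <- esearch("microglia depletion", retmax = 10, cfg = mock_cfg())
  expect_identical(r$uids[1:2], c("200299005", "200279739"))
  expect_lte(length(r$uids), 10)
})

test_that("retmax truncates the UID list", {
  r <- esearch("microglia depletion", retmax = 2, cfg = mock_cfg())
  expect_identical(r$uids, c("200299005", "200279739"))
  expect_gte(r$count, 2L)
})

test_that("request preconditions are enforced before any request", {
  expect_error(esearch("x", retmax = 0, cfg = mock_cfg()),
               class = "eutils_request_error")
  expect_error(esearch("", cfg = mock_cfg()), class = "eutils_request_error")
  expect_error(esearch("x", db = "pubmed", cfg = mock_cfg()),
               class = "eutils_request_error")
  expect_error(esummary(character(0), cfg = mock_cfg()),
               class = "eutils_request_error")
})

test_that("esummary resolves fixture UIDs to their accessions in order", {
  s <- esummary(c("200299005", "200271535"), cfg = mock_cfg())
  expect_length(s$records, 2)
  expect_identical(s$records[[1]]$accession, "GSE299005")
  expect_identical(s$records[[2]]$accession, "GSE271535")
  expect_identical(s$records[[1]]$organism, "Mus musculus")
  expect_identical(s$records[[1]]$accession_type, "series")
  expect_length(s$unresolved, 0)
})

test_that("unknown UIDs are reported in the side list, not dropped silently", {
  s <- esummary(c("200299005", "999999999"), cfg = mock_cfg())
  expect_length(s$records, 1)
  expect_identical(s$unresolved, "999999999")
})

test_that("a transient 500 is retried once and then succeeds", {
  flaky <- start_server("eutils", args = list(
    script = default_eutils_script(
      inject = list(list(route = "esearch", status = 500))
    )
  ))
  cfg <- eutils_config(base_url = flaky$base_url, min_interval = 0.01)
  r <- esearch("microglia depletion", retmax = 5, cfg = cfg)
  expect_identical(r$uids[1], "200299005")
  log <- parse_json(rawToChar(
    curl::curl_fetch_memory(paste0(flaky$base_url, "/__log"))$content
  ))
  expect_identical(log$esearch, 2L)
})

test_that("persistent failures and garbage bodies surface as typed errors", {
  broken <- start_server("eutils", args = list(
    script = default_eutils_script(inject = list(
      list(route = "esearch", status = 500),
      list(route = "esearch", status = 500),
      list(route = "esearch", status = 200, body = "<<<not parseable>>>")
    ))
  ))
  cfg <- eutils_config(base_url = broken$base_url, min_interval = 0.01)
  expect_error(esearch("anything", cfg = cfg), class = "eutils_upstream_error")
  err <- tryCatch(esearch("anything", cfg = cfg), error = function(e) e)
  expect_s3_class(err, "eutils_parse_error")
  expect_match(conditionMessage(err), "unparseable")
})

test_that("XML-shaped responses are parsed via the fallback path", {
  xml_body <- paste0(
    "<?xml version=\"1.0\"?><eSearchResult><Count>2</Count>",
    "<IdList><Id>200299005</Id><Id>200279739</Id></IdList>",
    "<QueryTranslation>q</QueryTranslation></eSearchResult>"
  )
  xml_mock <- start_server("eutils", args = list(
    script = default_eutils_script(inject = list(
      list(route = "esearch", status = 200, body = xml_body)
    ))
  ))
  cfg <- eutils_config(base_url = xml_mock$base_url, min_interval = 0.01)
  r <- esearch("whatever", retmax = 5, cfg = cfg)
  expect_identical(r$uids, c("200299005", "200279739"))
  expect_identical(r$count, 2L)
})
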