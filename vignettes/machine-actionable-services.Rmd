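---
title: "Machine-actionable service discovery and GEO tooling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Machine-actionable service discovery and GEO tooling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Most bioinformatics web resources are designed for human users. An
autonomous agent that wants to *find a dataset, judge its relevance, and
download it* has to scrape HTML or reverse-engineer ad-hoc JSON routes —
brittle, undocumented, and unreproducible. `biocrumbs` implements two
pieces of machine-actionable infrastructure: a lightweight metadata
format (*breadcrumbs*) that lets any service advertise its capabilities
inside the pages it already serves, and a concrete Model Context
Protocol (MCP) tool suite for the Gene Expression Omnibus (GEO) built on
NCBI's E-utilities. Everything is testable offline against a scripted
mock harness that ships with the package.

## The breadcrumb format

A breadcrumb is one HTML comment whose first token is the sentinel
`mcp-breadcrumb`, followed by a single JSON object:

```
<!-- mcp-breadcrumb
{"service": {"name": "demo-service", "version": "1.2.0"},
 "mcp_available": {"status": false},
 "endpoints": [{"method": "GET", "url": "/api/search",
                "concept": "search_data",
                "params": [{"name": "gene", "value_type": "string",
                            "required": true}]}]}
-->
```

The schema has three parts: service identity (`name`, `version`, both
required), MCP availability (`status`, with an absolute `redirect_url`
required whenever `status` is true), and fallback endpoints (method
drawn from GET/POST/PUT/DELETE, an absolute or root-relative URL, a
non-empty concept tag, typed parameters, an optional example URL).
`endpoints` may be empty only when a native MCP endpoint exists —
otherwise the document advertises nothing actionable and is rejected.

Design choices worth recording:

* **Validation is all-or-nothing.** `validate_document()` walks the raw
  mapping and collects *every* violated field path
  (`service.name`, `endpoints[2].method`, …; indices 1-based) before
  failing; no partial document is ever produced. Unknown extra fields are
  ignored for forward compatibility. The validator is hand-written rather
  than delegated to a JSON-Schema engine: full-path error reporting on
  arbitrary input is the contract, and the closed schema is small enough
  that an explicit walk is clearer than a schema interpreter.
* **Escaping.** A JSON payload may legitimately contain the HTML comment
  terminator `-->` inside strings, which would end the comment early.
  `render_comment()` rewrites every occurrence in the serialized text as
  the JSON unicode escape `--\u003e`. Because `>` can only occur inside
  JSON strings, the rewrite is exact, and standard JSON parsing restores
  the original characters; the round-trip is covered by randomized tests.
  If a terminator survived escaping the renderer would refuse to emit
  (that state is unreachable, but the guard documents the invariant).
* **Multiple breadcrumbs on one page.** The first *valid* document wins;
  later documents and invalid candidates are surfaced as warnings. This
  keeps discovery deterministic when services redundantly embed metadata
  across page fragments.
* **Concept tags are plain strings** (`search_data`, `download_file`),
  with an optional `concept_iris` list for ontology identifiers.
  Membership in a controlled vocabulary is deliberately not enforced:
  the tags are attachment points, and prematurely pinning a vocabulary
  would freeze the wrong thing.
* **Extraction is total.** `extract_candidates()` is a regular-expression
  scan that never raises, whatever bytes it is given — fuzz tests feed it
  truncated comments, nested comment-like sequences and random noise. The
  sentinel must be the comment's first token; `mcp-breadcrumbs` (longer
  token) does not match.

## The discovery ladder

`decide()` is a pure function from a fetch result to exactly one of four
outcomes, in strict priority order: native MCP redirect ≻ API
specification ≻ manual exploration ≻ discovery error (with malformed
metadata dominating absent metadata). Purity matters: the same page text
always yields the same outcome, which the tests verify over the scenario
matrix and hybrid pages (valid endpoints *and* `status: true` — redirect
wins).

`discover()` adds the network policy: a 10 s deadline, up to 5 HTTP
redirects, and two retries with 0.5 s / 1 s backoff on connection errors
and 5xx answers. A 5xx that survives the retries is reported as a
`discovery_error` with cause `http`; timeouts and connection failures
carry causes `timeout` and `network`. The executor (`execute_endpoint()`)
serializes GET/DELETE parameters as URL-encoded query pairs and POST/PUT
parameters as a JSON body — the format an API behind a JSON-first portal
most plausibly expects — with a 30 s default deadline. Authentication is
never attempted: endpoints answering 401/403 are returned verbatim,
because static metadata can document but not perform an authentication
flow.

## The E-utilities client and its rate limiter

Two endpoints are wrapped: ESearch (UID lists for a term over the `gds`
and `geoprofiles` databases) and ESummary (batched per-UID document
summaries). Every request carries the configured contact email; an API
key is appended when present. Responses are parsed as JSON first with an
XML fallback.

The rate limiter is a *pure scheduling function*:
`acquire_slot(state, now, keyed)` returns the smallest non-negative wait
such that the granted time is at least `min_interval` (default 0.1 s)
after the previous grant, and — when keyed — at most `ceiling`
(default 10) grants fall in any trailing 1-second window. Windows are
half-open `(t-1, t]`: with the default 0.1 s spacing the window ceiling
is exactly saturated and never binds, which mirrors the published
constants (a 0.1 s delay *is* 10 requests/second); the ceiling becomes
active only if an operator lowers `min_interval`. No clock is read inside
the function, so tests drive it on a simulated clock and compare entire
schedules against a brute-force grid scheduler. Under a burst the
caller's clock may trail the last granted slot; the grant is then
scheduled into the future and the returned wait covers the difference.

One upstream nuance is documented rather than resolved: the live
service's published unkeyed allowance is stricter than a flat 0.1 s
delay. The package implements the flat delay as the default and leaves
`min_interval` operator-configurable upward.

An empty UID list is a *normal* result, structurally distinct from an
upstream error — the calling agent is expected to reformulate and retry,
and the bundled transcript script encodes exactly that refinement loop
(four empty searches, then a broad term whose UID list begins
`200299005, 200279739`).

## The eight-tool GEO suite

Six search tools share one input schema (`term` required, `retmax`
optional, default 20, hard cap 500). Targeted tools rewrite queries:
profiles route to the `geoprofiles` database; datasets/series/samples/
platforms stay on `gds` with an entry-type filter (`AND GSE[ETYP]` and
so on) appended to the term. Every non-empty search is enriched with one
batched ESummary call — two upstream requests per tool call, no more —
and the returned accessions are sorted into five buckets by prefix
(GSE→series, GSM→samples, GPL→platforms, GDS→datasets, else other;
case-sensitive on the trimmed string, so `gse1` lands in `other`). The
buckets provably partition the input. Numeric UIDs are never used for
categorization: whether a UID's digit prefix encodes its record type is
undocumented upstream, so categorization always runs on accession
strings from summary records.

Responses are wrapped uniformly: one text block carrying the canonical
JSON payload plus a human-readable summary line, so both an LLM and its
human supervisor can read the same answer. `parse(wrap(x))` is the
identity, property-tested over random payloads.

## Download safety

`download_geo_data` constructs the archive URL from per-bucket templates
(`{acc}` = accession, `{stub}` = accession with its last three digits
replaced by `nnn`, matching the upstream directory layout; the templates
are configurable, which is also how the mock file server substitutes for
the live archive). Admission control applies three inequalities in
order: per-file limit (5 GB default) against the advertised
Content-Length from a HEAD probe, total-storage limit (10 GB) against an
on-disk scan of the root directory, and a free-space margin (100 MB).
The on-disk scan — rather than a session counter — makes the total limit
a property of the storage that survives restarts; metadata XML files
count toward it (the conservative reading). A rejected job writes zero
bytes.

When a server does not advertise a length the job is admitted
conservatively and the transfer is killed the moment written bytes
exceed the per-file limit; the partial file is removed. Transfers run in
a connection pool capped at 3 parallel transfers (observable in tests
against an instrumented slow mock), each with a 300 s deadline. Every
path the subsystem touches passes `validate_path()`: a lexical
canonicalization (resolving `.`/`..` without filesystem access, so
escapes are caught even for paths that do not exist yet) followed by a
root-prefix check. Acceptance is fuzz-tested against an independent
textual-reduction oracle. Free disk space is probed with `df`; where
that is unavailable the margin check is skipped at enqueue time while
the pure decision function retains it.

After a completed transfer the accession's ESummary record is fetched
(via an `accession[ACCN]` search) and written as `metadata.xml` next to
the archive; if the lookup fails, the XML records the accession and a
note instead, so the artifact pair is always complete.

The SOFT reader is deliberately minimal: entity headers (`^`), attribute
lines (`!`, including bare marker lines kept as flag attributes), column
definitions (`#`), and tab-delimited table rows, with a format error
naming the line number when structure is impossible (an attribute before
any entity). Lines the format does not define are preserved as raw
attributes rather than dropped. This supports inspecting what a download
produced; quantitative re-analysis of expression matrices is out of
scope. The writer exists for the harness and the round-trip property
(generator → writer → reader recovers structure exactly).

## Transports

Both registries — eight GEO tools, three discovery tools — are served
over newline-delimited JSON-RPC on standard streams and over HTTP, from
the *same* registry object, which makes transport equivalence a
structural guarantee and a tested one (payload-identical results for
fixed inputs). The stdio loop answers `initialize` with a pinned
protocol version before any tool call, and maps malformed frames to
protocol errors (−32700 parse, −32600 invalid, −32601 unknown method,
−32602 unknown tool); a corpus of hostile frames leaves the server
serving. Handler exceptions become tool-level error responses, never a
transport crash.

The HTTP mode exposes `POST /tools/<name>` (body mirroring the tool's
input schema — a mechanical, schema-driven mapping), `GET /tools`, an
OpenAPI 3.0.3 description, permissive CORS on every response, `/health`
(liveness, registry size, configuration-fallback flag; a failed registry
reports `degraded` while staying alive), and `/events?job_id=` — a
server-sent-event stream of download progress. Download tools are
exposed on both transports for equivalence. The event stream is
*bounded*: progress events are collected while the transfer pool is
driven (on state change and at 1 s intervals) and the complete
`text/event-stream` body is returned when the job reaches a terminal
state. A bounded stream keeps the route deterministic and testable;
true incremental flushing would tie the response lifetime to the
server's event loop without changing what a client observes for
finite jobs. Preflight requests are answered with HTTP 200 rather than
204 — an empty 204 through the embedded server corrupts keep-alive
framing for some clients, and nothing in CORS requires 204.

## The mock harness

The harness emulates exactly what the package's contracts need and no
more: five deterministic scenario pages (no breadcrumbs / valid /
malformed / native-MCP redirect / hybrid), plus `/flaky` (two 500s, then
success — one more failure than the retry schedule forgives would fail)
and `/slow` (never answers); a scripted E-utilities emulator with
term→UID and UID→summary tables, accession lookups, and FIFO failure
injections (status, garbage body, delay); and a file server with
spoofable Content-Length (so multi-gigabyte limits are exercised without
multi-gigabyte fixtures), suppressible length headers, per-file response
delays, and an in-flight-connection counter that makes the client's
concurrency bound observable. Servers run in a background R process so
the foreground session can block on client calls without event-loop
deadlock.

The UID→accession table (200299005→GSE299005, 200271535→GSE271535, …)
is a harness convention chosen so every scripted UID resolves to a
plausible series accession. What the harness does *not* emulate:
JavaScript-rendered pages, authentication flows, upstream rate-limit
headers, maintenance pages, or network jitter beyond the scripted
delays. Passing tests therefore demonstrate contract conformance — the
ladder, the limits, the schemas — not robustness against every
production failure mode of the live services.

## Problem sizes and test budget

The suite favors many small, fast cases: 40-document round-trip fuzz,
200-case extraction fuzz, 1000-string categorization and path-validation
fuzz, 500 randomized admission triples, 25-request limiter bursts
checked against the brute-force scheduler, 25 SOFT round-trips, and
five-transfer download bursts over ~20 kB bodies with 0.4 s server
delays. These sizes exercise every branch while keeping the whole suite
around a minute on one CPU; the acceptance script re-derives its
quantities in a few seconds.

## Known limitations

* Breadcrumb discovery reads static page text; services that render
  metadata client-side are invisible to it. A read-side manifest at
  `/.well-known/llm-manifest.json` with the identical JSON body is the
  more robust channel where available.
* No cryptographic signing or publisher verification: a page can claim
  anything. Agents should treat discovered metadata as a hint, not an
  authority.
* The download manager does not resume partial transfers, fetch
  supplementary (non-SOFT) files, or verify checksums (none are
  published for these archives).
* The E-utilities client covers ESearch/ESummary only; EFetch/ELink and
  WebEnv history sessions are out of scope.
* Provenance (who called which tool when, with what versions) is not
  tracked; the response payloads carry enough identifiers to build such
  an audit trail on top.
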