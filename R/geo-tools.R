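# The eight-tool GEO MCP suite: tool descriptors with JSON Schema
# contracts, targeted search dispatch over the E-utilities client,
# accession categorization, and MCP response wrapping.

GEO_SEARCH_TOOLS <- c(
  "search_geo", "search_geo_profiles", "search_geo_datasets",
  "search_geo_series", "search_geo_samples", "search_geo_platforms"
)
GEO_DOWNLOAD_TOOLS <- c("download_geo_data", "get_download_status")

RETMAX_DEFAULT <- 20L
RETMAX_CAP <- 500L

# Query rewriting per targeted tool: profiles route to the geoprofiles
# database; the typed searches stay on gds with an entry-type filter
# appended to the term.
search_dispatch <- function(tool_name, term) {
  switch(tool_name,
    search_geo = list(db = "gds", term = term),
    search_geo_profiles = list(db = "geoprofiles", term = term),
    search_geo_datasets = list(db = "gds", term = paste0(term, " AND GDS[ETYP]")),
    search_geo_series = list(db = "gds", term = paste0(term, " AND GSE[ETYP]")),
    search_geo_samples = list(db = "gds", term = paste0(term, " AND GSM[ETYP]")),
    search_geo_platforms = list(db = "gds", term = paste0(term, " AND GPL[ETYP]")),
    stop(bc_error("geo_tool_error", sprintf("unknown search tool '%s'", tool_name)))
  )
}

search_schema <- function() {
  list(
    type = "object",
    properties = list(
      term = list(type = "string", description = "Query term for the GEO databases."),
      retmax = list(
        type = "integer", minimum = 1, maximum = RETMAX_CAP,
        default = RETMAX_DEFAULT,
        description = "Maximum number of records to return."
      )
    ),
    required = list("term")
  )
}

search_output_schema <- function() {
  list(
    type = "object",
    properties = list(
      tool = list(type = "string"),
      term = list(type = "string"),
      count = list(type = "integer"),
      uids = list(type = "array", items = list(type = "string")),
      records = list(type = "array"),
      categorized = list(
        type = "object",
        properties = list(
          series = list(type = "array"), samples = list(type = "array"),
          platforms = list(type = "array"), datasets = list(type = "array"),
          other = list(type = "array")
        )
      )
    ),
    required = list("tool", "term", "count", "uids")
  )
}

tool_descriptor <- function(name, description, input_schema, output_schema,
                            concepts) {
  structure(
    list(
      name = name, description = description,
      input_schema = input_schema, output_schema = output_schema,
      concepts = concepts
    ),
    class = "tool_descriptor"
  )
}

#' List the GEO tool descriptors
#'
#' The registry of the eight-tool GEO suite. Six core search tools —
#' universal search across all GEO record types (`search_geo`) and the
#' targeted searches for gene expression profiles, curated datasets,
#' experimental series, individual samples, and platform definitions — and
#' two data-management tools (`download_geo_data`, `get_download_status`).
#' Every descriptor carries a JSON Schema for its inputs and outputs with
#' required vs optional parameters stated explicitly, plus semantic concept
#' tags (plain strings, placeholders for ontology-backed identifiers).
#'
#' @return A list of exactly eight `tool_descriptor` objects, stable across
#'   calls and transports.
#' @export
geo_list_tools <- function() {
  target <- c(
    search_geo = "all GEO record types",
    search_geo_profiles = "gene expression profiles",
    search_geo_datasets = "curated datasets (GDS)",
    search_geo_series = "experimental series (GSE)",
    search_geo_samples = "individual samples (GSM)",
    search_geo_platforms = "platform definitions (GPL)"
  )
  concept <- list(
    search_geo = list("search_data"),
    search_geo_profiles = list("search_data", "gene_expression_profile"),
    search_geo_datasets = list("search_data", "curated_dataset"),
    search_geo_series = list("search_data", "gene_expression_series"),
    search_geo_samples = list("search_data", "sample_record"),
    search_geo_platforms = list("search_data", "platform_definition")
  )
  searches <- lapply(GEO_SEARCH_TOOLS, function(nm) {
    tool_descriptor(
      name = nm,
      description = sprintf(
        "Search %s in the Gene Expression Omnibus. Returns matching UIDs with record metadata, categorized by accession type (GSE/GSM/GPL/GDS). An empty result is normal: refine the term and search again.",
        target[[nm]]
      ),
      input_schema = search_schema(),
      output_schema = search_output_schema(),
      concepts = concept[[nm]]
    )
  })
  downloads <- list(
    tool_descriptor(
      name = "download_geo_data",
      description = "Download the SOFT archive for a GEO accession (with XML metadata preserved alongside), subject to per-file/total-storage size limits and bounded concurrency. Returns a job id for status monitoring.",
      input_schema = list(
        type = "object",
        properties = list(
          accession = list(
            type = "string",
            pattern = "^(GSE|GSM|GPL|GDS)[0-9]+$",
            description = "GEO accession, e.g. GSE271535."
          ),
          wait = list(
            type = "boolean", default = TRUE,
            description = "Drive the transfer to completion before returning."
          )
        ),
        required = list("accession")
      ),
      output_schema = list(
        type = "object",
        properties = list(
          job_id = list(type = "string"),
          state = list(type = "string"),
          accession = list(type = "string")
        ),
        required = list("job_id", "state")
      ),
      concepts = list("download_file")
    ),
    tool_descriptor(
      name = "get_download_status",
      description = "Report the state and byte counts of one download job (by id) or of all tracked jobs.",
      input_schema = list(
        type = "object",
        properties = list(
          job_id = list(type = "string", description = "Job id; omit for all jobs.")
        ),
        required = list()
      ),
      output_schema = list(
        type = "object",
        properties = list(jobs = list(type = "array")),
        required = list("jobs")
      ),
      concepts = list("monitor_download")
    )
  )
  c(searches, downloads)
}

#' Categorize GEO accessions into record-type buckets
#'
#' Prefix mapping on the trimmed accession string: `GSE` to series, `GSM`
#' to samples, `GPL` to platforms, `GDS` to datasets, anything else
#' (including lowercase forms) to `other`. The five buckets always
#' partition the input: every element lands in exactly one bucket.
#'
#' @param accessions Character vector (or list) of accession strings.
#' @return A `categorized_results` list with elements `series`, `samples`,
#'   `platforms`, `datasets`, `other`.
#' @export
categorize_accessions <- function(accessions) {
  accessions <- vapply(accessions, as.character, character(1), USE.NAMES = FALSE)
  accessions <- trimws(accessions)
  type <- accession_type(accessions)
  buckets <- lapply(
    c(series = "series", samples = "samples", platforms = "platforms",
      datasets = "datasets", other = "other"),
    function(t) as.list(accessions[type == t])
  )
  structure(buckets, class = "categorized_results")
}

#' Wrap a structured result as an MCP tool response
#'
#' Builds the response shape every tool returns: a list of text content
#' blocks, each carrying the canonical JSON payload plus a human-readable
#' summary line, with deterministic ordering. The payload parses back to
#' the structured result.
#'
#' @param payload A serializable structured result.
#' @param summary Optional summary line; derived from the payload when
#'   omitted.
#' @param is_error Mark the response as a tool-level error.
#' @return A `tool_response` with a `content` list; each block has `type`
#'   (`"text"`), `summary`, `json` (canonical payload text) and `text`
#'   (summary and payload joined).
#' @export
wrap_response <- function(payload, summary = NULL, is_error = FALSE) {
  json <- canonical_json(payload)
  if (is.null(summary)) summary <- summarize_payload(payload)
  stopifnot(is_nonempty_string(summary))
  block <- list(
    type = "text",
    summary = summary,
    json = json,
    text = paste(summary, json, sep = "\n")
  )
  structure(
    list(content = list(block), is_error = isTRUE(is_error)),
    class = "tool_response"
  )
}

summarize_payload <- function(payload) {
  if (is.list(payload) && !is.null(payload$categorized)) {
    sizes <- vapply(payload$categorized, length, integer(1))
    total <- sum(sizes)
    return(sprintf(
      "%d result(s) for '%s': %s", total, payload$term %||% "",
      paste(sprintf("%s %d", names(sizes), sizes), collapse = ", ")
    ))
  }
  if (is.list(payload) && !is.null(payload$count)) {
    return(sprintf("%s result(s)", payload$count))
  }
  "result"
}

#' @export
print.tool_response <- function(x, ...) {
  for (b in x$content) cat(b$text, "\n")
  invisible(x)
}

#' Run one of the six GEO search tools
#'
#' Dispatches to [esearch()] with the tool's database/entry-type rewriting,
#' enriches non-empty UID lists with one batched [esummary()] call,
#' categorizes the returned accessions, and wraps everything as a
#' [wrap_response()] tool response. An empty result is a well-formed
#' zero-hit response, not an error; upstream failures surface as
#' informative tool-level error responses rather than a transport crash.
#'
#' @param tool_name One of the six search tool names.
#' @param term Query term.
#' @param retmax Result cap (default 20, hard cap 500).
#' @param cfg An [eutils_config()].
#' @return A `tool_response`.
#' @export
run_search_tool <- function(tool_name, term, retmax = RETMAX_DEFAULT,
                            cfg = eutils_config()) {
  if (!(tool_name %in% GEO_SEARCH_TOOLS)) {
    stop(bc_error("geo_tool_error",
                  sprintf("'%s' is not a search tool", tool_name)))
  }
  if (!is_count(retmax) || retmax < 1 || retmax > RETMAX_CAP) {
    return(wrap_response(
      list(tool = tool_name, term = term,
           error = sprintf("retmax must be between 1 and %d", RETMAX_CAP)),
      summary = sprintf("invalid retmax for %s", tool_name),
      is_error = TRUE
    ))
  }
  d <- search_dispatch(tool_name, term)
  out <- tryCatch({
    sr <- esearch(d$term, db = d$db, retmax = retmax, cfg = cfg)
    records <- list()
    unresolved <- character(0)
    if (length(sr$uids) > 0L) {
      es <- esummary(sr$uids, db = d$db, cfg = cfg)
      records <- es$records
      unresolved <- es$unresolved
    }
    accs <- vapply(records, function(r) r$accession, character(1))
    payload <- list(
      tool = tool_name,
      term = term,
      query_sent = d$term,
      db = d$db,
      count = sr$count,
      uids = as.list(sr$uids),
      records = lapply(records, unclass),
      unresolved = as.list(unresolved),
      categorized = unclass(categorize_accessions(accs))
    )
    wrap_response(payload)
  }, biocrumbs_error = function(e) {
    wrap_response(
      list(tool = tool_name, term = term, error = conditionMessage(e),
           error_class = class(e)[1]),
      summary = sprintf("%s failed: %s", tool_name, conditionMessage(e)),
      is_error = TRUE
    )
  })
  out
}
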