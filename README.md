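# biocrumbs

Bioinformatics web servers are built for people: rich interfaces, plots,
click-through exploration. Autonomous research agents built on large
language models need something different — a machine-actionable contract
that says what a service can do, how to call it, and what the result
means. `biocrumbs` implements that service layer in R, for two
complementary situations:

* **Services without native machine interfaces** get *breadcrumbs*:
  a small JSON document embedded in an HTML comment that advertises the
  service's identity, whether a native Model Context Protocol (MCP)
  endpoint exists, and a fallback API specification (endpoints with HTTP
  method, a semantic concept tag such as `search_data`, and typed
  parameter schemas). A three-tool discovery server applies a strict
  graceful-degradation ladder to any URL:

  1. native MCP advertised (`mcp_available.status: true`) → redirect there;
  2. else valid breadcrumb endpoints → expose the API specification;
  3. else no breadcrumbs → "manual exploration required";
  4. breadcrumbs present but malformed → an informative validation error,
     never a silent failure.

* **GEO (Gene Expression Omnibus)** gets an eight-tool MCP suite layered
  over NCBI E-utilities: a universal search (`search_geo`), five targeted
  searches (profiles, datasets, series, samples, platforms), and two
  data-management tools (`download_geo_data`, `get_download_status`).
  The client enforces a 0.1 s inter-request delay (10 requests/second
  ceiling when an API key is configured), categorizes results by
  accession prefix (GSE/GSM/GPL/GDS), and downloads SOFT archives under
  strict safety controls: path validation confined to a root directory,
  5 GB per-file and 10 GB total-storage limits, at most 3 parallel
  transfers, a 300 s transfer timeout, and XML metadata preserved next to
  every archive. A minimal SOFT reader inspects what was downloaded.

Both tool registries are served over two transports — newline-delimited
JSON-RPC on standard streams (for MCP clients such as Claude Desktop) and
an HTTP mode with OpenAPI description, CORS, a server-sent-event stream
for download progress, and a `/health` probe. A scripted mock harness
(scenario pages, an E-utilities emulator, a controllable file server)
makes every behavior testable with no network access.

## Worked example

Discover a service and search GEO, entirely against the bundled mock
harness:

```r
library(biocrumbs)

pages <- mock_server("pages")
out <- discover(paste0(pages$base_url, "/valid"))
print(out)
#> <discovery_outcome> api_specification
#> Service: demo-service 1.2.0 (no native MCP; fallback API specification)
#> GET /api/search [search_data] params: gene*(string), limit(integer)
#> GET /api/download [download_file] params: id*(string)
pages$stop()
```

The discovery ladder classified the page as an API specification (no
native MCP endpoint) and reconstructed human-readable API documentation
from the embedded JSON: two endpoints, each with its method, concept tag
and parameter signature (`*` marks required parameters).

```r
es <- mock_server("eutils")
cfg <- eutils_config(base_url = es$base_url, min_interval = 0.01)
resp <- run_search_tool("search_geo", "microglia depletion", 10, cfg)
cat(resp$content[[1]]$summary, "\n")
#> 7 result(s) for 'microglia depletion': series 7, samples 0, platforms 0, datasets 0, other 0
p <- parse_json(resp$content[[1]]$json)
head(unlist(p$categorized$series), 3)
#> [1] "GSE299005" "GSE279739" "GSE271535"
es$stop()
```

The search tool ran one ESearch plus one batched ESummary call, resolved
the UIDs to accessions, and sorted all seven hits into the series bucket.
A search that matches nothing returns a well-formed zero-hit response —
an empty UID list is a normal result the calling agent is expected to
refine, not an error.

To run the servers from a shell:

```sh
Rscript inst/scripts/geo-mcp-server.R                 # stdio MCP mode
Rscript inst/scripts/geo-mcp-server.R --http --port 8765
Rscript inst/scripts/breadcrumbs-mcp-server.R
```

User configuration (email, optional API key, download directory) lives in
`~/.geo-mcp/config.json`; missing files or fields fall back to defaults
with a warning.

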