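Package: biocrumbs
Title: Machine-Actionable Service Discovery and GEO Tooling for LLM Agents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A machine-actionable service layer for bioinformatics web
    resources. Implements the 'breadcrumbs' format: structured JSON metadata
    embedded in HTML comments that advertises a service's identity, native
    Model Context Protocol (MCP) availability, and fallback API endpoints,
    together with a discovery protocol that degrades gracefully (MCP redirect,
    API specification, manual exploration, informative errors). Also provides
    a rate-limited NCBI E-utilities client (ESearch/ESummary over the GEO
    databases), an eight-tool GEO MCP suite with accession categorization,
    a safety-controlled download manager for SOFT archives with a minimal
    SOFT reader, stdio and HTTP MCP transports, and a scripted mock-service
    harness so everything is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    curl,
    httpuv,
    later,
    promises,
    callr,
    xml2,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
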