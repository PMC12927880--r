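# Minimal reader/writer for SOFT (Simple Omnibus Format in Text), the
# line-oriented archive format used for GEO record downloads. Only the
# structural skeleton is modelled: entity headers (^TYPE = id), attribute
# lines (!key = value), column definitions (#name = description), and
# tab-delimited table rows. That is sufficient to inspect what a download
# produced; quantitative re-analysis of expression tables is out of scope.

#' Read a SOFT file
#'
#' Parses a SOFT file (plain text or gzip; detected from the magic bytes)
#' into an ordered list of entities. Each entity carries its attributes (in
#' file order; repeated keys are kept as a vector) and, when present, a
#' column-named table. Lines of a type the format does not define are
#' preserved as raw attributes rather than dropped.
#'
#' @param path Path to a `.soft` / `.soft.gz` file.
#' @return A `soft_document`: list with `entities`, each
#'   `list(entity_type, entity_id, attributes, columns, table)` where
#'   `table` is a data.frame or `NULL`.
#' @export
read_soft <- function(path) {
  stopifnot(file.exists(path))
  con <- gzfile(path, "rt") # reads plain text transparently as well
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)

  entities <- list()
  cur <- NULL
  raw_n <- 0L

  flush_entity <- function(cur) {
    if (is.null(cur)) return(NULL)
    tab <- NULL
    if (length(cur$rows) > 0L) {
      cols <- cur$columns
      if (length(cols) == 0L) {
        # no column definitions: first row is the header
        cols <- strsplit(cur$rows[[1]], "\t", fixed = TRUE)[[1]]
        cur$rows <- cur$rows[-1]
      }
      cells <- lapply(cur$rows, function(r) strsplit(r, "\t", fixed = TRUE)[[1]])
      widths <- unique(vapply(cells, length, integer(1)))
      if (length(widths) > 1L || (length(widths) == 1L && widths != length(cols))) {
        stop_soft_format(
          sprintf("inconsistent table width in entity %s", cur$entity_id),
          cur$first_row_line
        )
      }
      tab <- as.data.frame(
        do.call(rbind, cells),
        stringsAsFactors = FALSE
      )
      names(tab) <- cols
      rownames(tab) <- NULL
    }
    list(
      entity_type = cur$entity_type, entity_id = cur$entity_id,
      attributes = cur$attributes, columns = cur$columns, table = tab
    )
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    first <- substr(line, 1, 1)
    if (first == "^") {
      ent <- flush_entity(cur)
      if (!is.null(ent)) entities[[length(entities) + 1L]] <- ent
      kv <- split_kv(substring(line, 2))
      cur <- list(
        entity_type = kv$key, entity_id = kv$value,
        attributes = list(), columns = character(0), rows = list(),
        first_row_line = i
      )
    } else if (first == "!") {
      if (is.null(cur)) {
        stop_soft_format("attribute line before any entity header", i)
      }
      kv <- split_kv(substring(line, 2))
      if (is.null(kv$value)) {
        # marker lines such as table_begin/table_end: keep as flag attributes
        cur$attributes[[kv$key]] <- c(cur$attributes[[kv$key]], TRUE)
      } else {
        cur$attributes[[kv$key]] <- c(cur$attributes[[kv$key]], kv$value)
      }
    } else if (first == "#") {
      if (is.null(cur)) {
        stop_soft_format("column definition before any entity header", i)
      }
      kv <- split_kv(substring(line, 2))
      cur$columns <- c(cur$columns, kv$key)
    } else if (grepl("\t", line, fixed = TRUE) && !is.null(cur)) {
      if (length(cur$rows) == 0L) cur$first_row_line <- i
      cur$rows[[length(cur$rows) + 1L]] <- line
    } else {
      # unknown line type: preserved verbatim as a raw attribute
      if (is.null(cur)) {
        stop_soft_format("data line before any entity header", i)
      }
      raw_n <- raw_n + 1L
      cur$attributes[[sprintf(".raw%d", raw_n)]] <- line
    }
  }
  ent <- flush_entity(cur)
  if (!is.null(ent)) entities[[length(entities) + 1L]] <- ent

  structure(list(entities = entities), class = "soft_document")
}

split_kv <- function(x) {
  pos <- regexpr(" = ", x, fixed = TRUE)
  if (pos < 0) {
    pos2 <- regexpr("=", x, fixed = TRUE)
    if (pos2 < 0) return(list(key = trimws(x), value = NULL))
    return(list(
      key = trimws(substr(x, 1, pos2 - 1)),
      value = trimws(substring(x, pos2 + 1))
    ))
  }
  list(
    key = trimws(substr(x, 1, pos - 1)),
    value = substring(x, pos + 3)
  )
}

#' Write a SOFT file
#'
#' Inverse of [read_soft()] for documents built in code (used by the mock
#' harness and the round-trip tests): entity headers, attributes, column
#' definitions and tab-joined table rows, optionally gzip-compressed.
#'
#' @param doc A `soft_document` (or bare list with an `entities` field).
#' @param path Output path; compressed when `gzip = TRUE`.
#' @param gzip Write gzip-compressed output.
#' @return `path`, invisibly.
#' @export
write_soft <- function(doc, path, gzip = grepl("\\.gz$", path)) {
  lines <- character(0)
  for (e in doc$entities) {
    lines <- c(lines, sprintf("^%s = %s", e$entity_type, e$entity_id))
    for (k in names(e$attributes)) {
      for (v in e$attributes[[k]]) {
        lines <- c(lines,
          if (isTRUE(v)) sprintf("!%s", k) else sprintf("!%s = %s", k, v))
      }
    }
    for (col in e$columns) lines <- c(lines, sprintf("#%s = ", col))
    if (!is.null(e$table)) {
      if (length(e$columns) == 0L) {
        lines <- c(lines, paste(names(e$table), collapse = "\t"))
      }
      lines <- c(lines, apply(e$table, 1, paste, collapse = "\t"))
    }
  }
  con <- if (gzip) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
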