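# Safety-controlled retrieval of GEO SOFT archives: path validation
# confined to a root directory, pure admission control against size and
# disk limits, a bounded-concurrency transfer pool, per-job status
# tracking, and XML metadata preservation alongside each archive.

#' Download safety policy
#'
#' The limits governing admission and execution of download jobs. Defaults
#' follow the package's safety posture: 5 GB per file, 10 GB total
#' storage under the root, three parallel transfers, a 300 s per-request
#' timeout, and a 100 MB free-space margin.
#'
#' @param root_dir Root directory all downloads are confined to (created if
#'   needed).
#' @param per_file_limit Maximum bytes for a single archive.
#' @param total_limit Maximum bytes stored under `root_dir` in total.
#' @param max_concurrent Maximum simultaneous transfers.
#' @param request_timeout Per-transfer deadline in seconds.
#' @param free_space_margin Bytes of disk space that must remain free
#'   beyond the advertised size.
#' @return A `download_policy` object.
#' @export
download_policy <- function(root_dir,
                            per_file_limit = 5 * 1024^3,
                            total_limit = 10 * 1024^3,
                            max_concurrent = 3,
                            request_timeout = 300,
                            free_space_margin = 100 * 1024^2) {
  stopifnot(
    per_file_limit > 0, total_limit > 0, max_concurrent > 0,
    request_timeout > 0, free_space_margin >= 0
  )
  if (!dir.exists(root_dir)) {
    dir.create(root_dir, recursive = TRUE, showWarnings = FALSE)
  }
  if (!dir.exists(root_dir)) {
    stop_path(sprintf("root_dir %s does not exist and could not be created", root_dir))
  }
  structure(
    list(
      root_dir = normalizePath(root_dir),
      per_file_limit = per_file_limit, total_limit = total_limit,
      max_concurrent = as.integer(max_concurrent),
      request_timeout = request_timeout,
      free_space_margin = free_space_margin
    ),
    class = "download_policy"
  )
}

# Lexical path normalization: resolves "." and ".." segments without
# touching the filesystem, so escape attempts are caught even for paths
# that do not exist yet.
lexical_normalize <- function(path) {
  segs <- strsplit(path, "/", fixed = TRUE)[[1]]
  out <- character(0)
  absolute <- length(segs) > 0L && !nzchar(segs[1])
  for (s in segs) {
    if (!nzchar(s) || s == ".") next
    if (s == "..") {
      if (length(out) > 0L && out[length(out)] != "..") {
        out <- out[-length(out)]
      } else if (!absolute) {
        out <- c(out, "..")
      }
      # ".." at an absolute root stays at the root
    } else {
      out <- c(out, s)
    }
  }
  paste0(if (absolute) "/" else "", paste(out, collapse = "/"))
}

#' Validate a candidate path against a root directory
#'
#' Security gate for every filesystem operation the download subsystem
#' performs: the candidate (relative to `root`, or absolute) is lexically
#' canonicalized — `.` and `..` segments resolved without filesystem
#' access — and accepted only if the result is still within `root`.
#' Rejection signals `bc_path_error`, a security condition distinct from
#' any I/O failure.
#'
#' @param root Root directory (must be canonicalizable).
#' @param candidate Path to validate; relative paths are interpreted
#'   against `root`.
#' @return The canonical absolute path, inside `root`.
#' @export
validate_path <- function(root, candidate) {
  root <- normalizePath(root, mustWork = TRUE)
  if (!is_string(candidate) || !nzchar(candidate)) {
    stop_path("candidate path must be a non-empty string", candidate)
  }
  full <- if (startsWith(candidate, "/")) candidate else file.path(root, candidate)
  norm <- lexical_normalize(full)
  if (!(norm == root || startsWith(norm, paste0(root, "/")))) {
    stop_path(
      sprintf("path '%s' escapes the download root '%s'", candidate, root),
      candidate
    )
  }
  norm
}

#' Admission decision for a download job
#'
#' Pure re-statement of the three safety inequalities, applied in order:
#' reject with reason `per_file` when the advertised size exceeds the
#' per-file limit; with reason `total` when current usage plus the
#' advertised size would exceed the total-storage limit; with reason
#' `disk` when free disk space is below the advertised size plus the
#' margin; otherwise admit. An unknown advertised size (`NA`) is admitted
#' conservatively — the transfer is aborted later the moment written bytes
#' exceed the per-file limit.
#'
#' @param policy A [download_policy()].
#' @param advertised_size Bytes announced by the server (`NA` if unknown).
#' @param current_usage Bytes currently stored under the root.
#' @param free_space Free bytes on the target filesystem (`NA` skips the
#'   disk check).
#' @return `list(admit = TRUE)` or `list(admit = FALSE, reason = <r>)`
#'   with `reason` in `c("per_file", "total", "disk")`.
#' @export
admit_job <- function(policy, advertised_size, current_usage, free_space) {
  size <- if (is.na(advertised_size)) 0 else advertised_size
  if (size > policy$per_file_limit) {
    return(list(admit = FALSE, reason = "per_file"))
  }
  if (current_usage + size > policy$total_limit) {
    return(list(admit = FALSE, reason = "total"))
  }
  if (!is.na(free_space) && free_space < size + policy$free_space_margin) {
    return(list(admit = FALSE, reason = "disk"))
  }
  list(admit = TRUE)
}

dir_usage_bytes <- function(root) {
  files <- list.files(root, recursive = TRUE, full.names = TRUE, all.files = TRUE)
  if (length(files) == 0L) return(0)
  sum(file.size(files), na.rm = TRUE)
}

free_disk_bytes <- function(path) {
  out <- tryCatch(
    suppressWarnings(system2("df", c("-Pk", shQuote(path)), stdout = TRUE, stderr = FALSE)),
    error = function(e) NULL
  )
  if (is.null(out) || length(out) < 2) return(NA_real_)
  fields <- strsplit(trimws(out[length(out)]), "[[:space:]]+")[[1]]
  if (length(fields) < 4) return(NA_real_)
  avail <- suppressWarnings(as.numeric(fields[4]))
  if (is.na(avail)) NA_real_ else avail * 1024
}

# Archive URL from the configured per-bucket template; {acc} is the
# accession, {stub} the accession with its last three digits as "nnn".
soft_archive_url <- function(accession, cfg) {
  bucket <- unname(accession_type(accession))
  if (bucket == "other") {
    stop(bc_error("geo_tool_error",
                  sprintf("'%s' is not a recognized GEO accession", accession)))
  }
  tpl <- cfg$soft_url_templates[[bucket]]
  stub <- sub("[0-9]{1,3}$", "nnn", accession)
  gsub("{acc}", accession, gsub("{stub}", stub, tpl, fixed = TRUE), fixed = TRUE)
}

#' Create a download manager
#'
#' Stateful coordinator for download jobs: admission control, a transfer
#' pool capped at `policy$max_concurrent` simultaneous connections, job
#' state tracking (`queued -> running -> completed|failed`, or
#' `queued -> rejected`), and metadata preservation. Jobs are enqueued with
#' [download_geo_data()] and advanced with `poll()`/`run_all()`;
#' [get_download_status()] reads a snapshot.
#'
#' @param policy A [download_policy()].
#' @param cfg An [eutils_config()] (archive URL templates and the ESummary
#'   lookup used to build the `metadata.xml` companion file).
#' @return A `download_manager` environment.
#' @export
download_manager <- function(policy, cfg = eutils_config()) {
  self <- new.env(parent = emptyenv())
  self$policy <- policy
  self$cfg <- cfg
  self$jobs <- list()
  self$pool <- curl::new_pool(
    total_con = policy$max_concurrent,
    host_con = policy$max_concurrent
  )
  self$counter <- 0L
  class(self) <- "download_manager"
  self
}

new_job <- function(self, accession) {
  self$counter <- self$counter + 1L
  job_id <- sprintf("job-%04d", self$counter)
  acc_dir <- validate_path(self$policy$root_dir, accession)
  job <- list(
    job_id = job_id, accession = accession, state = "queued",
    bytes_done = 0, advertised_size = NA_real_, error = NULL,
    archive_path = validate_path(
      self$policy$root_dir,
      file.path(accession, paste0(accession, "_family.soft.gz"))
    ),
    metadata_path = validate_path(
      self$policy$root_dir, file.path(accession, "metadata.xml")
    ),
    dir = acc_dir,
    created = Sys.time(), started = NULL, finished = NULL
  )
  self$jobs[[job_id]] <- job
  job_id
}

set_job <- function(self, job_id, ...) {
  patch <- list(...)
  job <- self$jobs[[job_id]]
  for (k in names(patch)) job[[k]] <- patch[[k]]
  self$jobs[[job_id]] <- job
  invisible(job)
}

# HEAD request for the advertised Content-Length; NA when the server does
# not announce one or the probe fails.
advertised_length <- function(url, timeout) {
  h <- curl::new_handle(nobody = TRUE, timeout = min(timeout, 30),
                        accept_encoding = "identity")
  res <- tryCatch(curl::curl_fetch_memory(url, handle = h), error = function(e) NULL)
  if (is.null(res)) return(NA_real_)
  len <- curl::parse_headers_list(res$headers)[["content-length"]]
  if (is.null(len)) NA_real_ else suppressWarnings(as.numeric(len))
}

#' Enqueue a GEO download
#'
#' Constructs the archive URL from the configured template, performs
#' admission control (per-file limit against the advertised
#' Content-Length, total-storage limit against an on-disk scan of the
#' root, free-space margin), and — when admitted — adds the transfer to
#' the bounded pool. A rejected job writes zero bytes and records the
#' admission reason. On completion both the SOFT archive and its
#' `metadata.xml` (built from the accession's ESummary record) are
#' persisted under `root_dir/<accession>/`.
#'
#' @param manager A [download_manager()].
#' @param accession GEO accession with a recognized prefix
#'   (GSE/GSM/GPL/GDS).
#' @param wait Drive the pool until this job reaches a terminal state.
#' @return The job id (character).
#' @export
download_geo_data <- function(manager, accession, wait = TRUE) {
  self <- manager
  if (!is_string(accession) || accession_type(accession) == "other") {
    stop(bc_error("geo_tool_error",
                  sprintf("'%s' is not a recognized GEO accession", accession)))
  }
  url <- soft_archive_url(accession, self$cfg)
  job_id <- new_job(self, accession)

  size <- advertised_length(url, self$policy$request_timeout)
  usage <- dir_usage_bytes(self$policy$root_dir)
  free <- free_disk_bytes(self$policy$root_dir)
  decision <- admit_job(self$policy, size, usage, free)
  if (!isTRUE(decision$admit)) {
    set_job(self, job_id,
      state = "rejected", finished = Sys.time(),
      error = sprintf("admission rejected: %s limit", decision$reason)
    )
    return(job_id)
  }
  set_job(self, job_id, advertised_size = size)

  dir.create(self$jobs[[job_id]]$dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(self$jobs[[job_id]]$archive_path, "wb")
  limit <- self$policy$per_file_limit

  h <- curl::new_handle(
    url = url,
    timeout = self$policy$request_timeout,
    accept_encoding = "identity", followlocation = TRUE
  )
  curl::multi_add(
    h,
    pool = self$pool,
    data = function(bytes, final) {
      job <- self$jobs[[job_id]]
      if (identical(job$state, "queued")) {
        set_job(self, job_id, state = "running", started = Sys.time())
      }
      done <- job$bytes_done + length(bytes)
      if (done > limit) {
        set_job(self, job_id, error = "per-file size limit exceeded mid-transfer")
        stop("per-file size limit exceeded")
      }
      writeBin(bytes, con)
      set_job(self, job_id, bytes_done = done)
    },
    done = function(res) {
      close(con)
      if (res$status_code >= 400) {
        unlink(self$jobs[[job_id]]$archive_path)
        set_job(self, job_id,
          state = "failed", finished = Sys.time(),
          error = sprintf("server answered HTTP %d", res$status_code)
        )
        return(invisible())
      }
      set_job(self, job_id, state = "completed", finished = Sys.time())
      write_metadata_xml(self, job_id)
    },
    fail = function(err) {
      try(close(con), silent = TRUE)
      unlink(self$jobs[[job_id]]$archive_path)
      job <- self$jobs[[job_id]]
      msg <- job$error %||% as.character(err)
      if (grepl("[Tt]ime.?out|timed out", msg)) {
        msg <- sprintf("transfer timed out after %ds", self$policy$request_timeout)
      }
      set_job(self, job_id,
        state = "failed", finished = Sys.time(),
        error = msg, bytes_done = 0
      )
    }
  )
  if (isTRUE(wait)) manager_wait(self, job_id)
  job_id
}

#' Drive the transfer pool
#'
#' `manager_poll()` advances pending transfers for at most `timeout`
#' seconds; `manager_wait()` polls until the given job (or every job)
#' reaches a terminal state. `multi_run()` can surface a data-callback
#' abort as its own error; that is treated as progress and draining
#' continues.
#'
#' @param self A [download_manager()].
#' @param timeout Seconds to service transfers for.
#' @param job_id Job id to wait for, or `NULL` for all jobs.
#' @param deadline Overall wait deadline in seconds.
#' @return `NULL`, invisibly.
#' @export
manager_poll <- function(self, timeout = 0.1) {
  # libcurl echoes data-callback aborts (the intended over-limit kill
  # switch) on stderr; discard that noise while draining
  utils::capture.output(
    res <- tryCatch(
      curl::multi_run(timeout = timeout, pool = self$pool),
      error = function(e) NULL
    ),
    type = "message"
  )
  invisible(NULL)
}

#' @rdname manager_poll
#' @export
manager_wait <- function(self, job_id = NULL, deadline = 600) {
  t0 <- monotonic_now()
  terminal <- c("completed", "failed", "rejected")
  pending <- function() {
    jobs <- if (is.null(job_id)) self$jobs else self$jobs[job_id]
    any(!vapply(jobs, function(j) j$state %in% terminal, logical(1)))
  }
  while (pending() && monotonic_now() - t0 < deadline) {
    manager_poll(self, timeout = 0.2)
  }
  invisible(NULL)
}

write_metadata_xml <- function(self, job_id) {
  job <- self$jobs[[job_id]]
  rec <- tryCatch({
    sr <- esearch(paste0(job$accession, "[ACCN]"), db = "gds", retmax = 1,
                  cfg = self$cfg)
    if (length(sr$uids) == 0L) NULL else {
      es <- esummary(sr$uids[1], db = "gds", cfg = self$cfg)
      if (length(es$records) > 0L) es$records[[1]] else NULL
    }
  }, error = function(e) NULL)

  doc <- xml2::xml_new_root("record")
  xml2::xml_set_attr(doc, "accession", job$accession)
  if (!is.null(rec)) {
    for (f in c("uid", "title", "summary", "organism", "entry_type")) {
      if (!is.null(rec[[f]])) {
        xml2::xml_add_child(doc, f, rec[[f]])
      }
    }
  } else {
    xml2::xml_add_child(
      doc, "note",
      "summary metadata unavailable at download time"
    )
  }
  xml2::write_xml(doc, job$metadata_path)
  invisible(job$metadata_path)
}

#' Download job status
#'
#' Snapshot of one job (by id) or of every tracked job. Unknown ids yield
#' a not-found record rather than an error, so status polling can never
#' crash a client loop.
#'
#' @param manager A [download_manager()].
#' @param job_id Job id, or `NULL` for all jobs.
#' @return A list of status records: `job_id`, `accession`, `state`,
#'   `bytes_done`, `error`. Unknown ids produce
#'   `list(job_id = ..., state = "not_found", error = ...)`.
#' @export
get_download_status <- function(manager, job_id = NULL) {
  snapshot <- function(j) {
    list(
      job_id = j$job_id, accession = j$accession, state = j$state,
      bytes_done = j$bytes_done, error = j$error
    )
  }
  if (is.null(job_id)) {
    return(unname(lapply(manager$jobs, snapshot)))
  }
  lapply(job_id, function(id) {
    j <- manager$jobs[[id]]
    if (is.null(j)) {
      list(job_id = id, state = "not_found",
           error = sprintf("no job with id '%s'", id))
    } else {
      snapshot(j)
    }
  })
}
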