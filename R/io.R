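#' Write one session to CSV
#'
#' Plain-text session dialect: six `key,value` header lines (subject_id,
#' timestamp_iso, fs_hz, sbp_ref_mmhg, dbp_ref_mmhg, hr_bpm) followed by an
#' `amplitude` column with one sample per line.
#'
#' @param record A [ppg_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(record, path) {
  header <- c(
    paste0("subject_id,", record$subject_id),
    paste0("timestamp_iso,", format(record$timestamp, "%Y-%m-%dT%H:%M:%OS3Z",
                                    tz = "UTC")),
    paste0("fs_hz,", format(record$fs, digits = 15)),
    paste0("sbp_ref_mmhg,", format(record$sbp_ref, digits = 15)),
    paste0("dbp_ref_mmhg,", format(record$dbp_ref, digits = 15)),
    paste0("hr_bpm,", format(record$hr_bpm, digits = 15)),
    "amplitude")
  writeLines(c(header, format(record$samples, digits = 15, trim = TRUE,
                              scientific = FALSE)), path)
  invisible(path)
}

#' Read one session CSV
#'
#' @param path File written by [write_session_csv()] (any single-channel CSV
#'   with the same header keys is accepted).
#' @return A [ppg_record()].
#' @export
read_session_csv <- function(path) {
  lines <- readLines(path)
  amp_at <- match("amplitude", lines)
  if (is.na(amp_at)) stop("schema error: no `amplitude` column in ", path,
                          call. = FALSE)
  kv <- strsplit(lines[seq_len(amp_at - 1L)], ",", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ","), character(1))
  need <- c("subject_id", "timestamp_iso", "fs_hz", "sbp_ref_mmhg",
            "dbp_ref_mmhg", "hr_bpm")
  miss <- setdiff(need, keys)
  if (length(miss)) {
    stop("schema error: missing header field(s) ",
         paste(miss, collapse = ", "), " in ", path, call. = FALSE)
  }
  h <- stats::setNames(vals, keys)
  val <- function(key) unname(h[[key]])
  samples <- as.numeric(lines[seq(amp_at + 1L, length(lines))])
  if (anyNA(samples)) stop("malformed amplitude values in ", path,
                           call. = FALSE)
  ppg_record(samples,
             fs = as.numeric(val("fs_hz")),
             subject_id = val("subject_id"),
             timestamp = as.POSIXct(val("timestamp_iso"),
                                    format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"),
             sbp_ref = as.numeric(val("sbp_ref_mmhg")),
             dbp_ref = as.numeric(val("dbp_ref_mmhg")),
             hr_bpm = as.numeric(val("hr_bpm")))
}

#' Write a cohort to disk
#'
#' One CSV per session plus a cohort manifest CSV (session_path, subject_id,
#' timestamp, sbp, dbp, hr).
#'
#' @param cohort A `ppg_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(cohort$records))
  for (i in seq_along(cohort$records)) {
    r <- cohort$records[[i]]
    paths[i] <- file.path(dir, sprintf("%s_%04d.csv", r$subject_id, i))
    write_session_csv(r, paths[i])
  }
  manifest <- data.frame(
    session_path = basename(paths),
    subject_id = cohort$manifest$subject_id,
    timestamp = format(cohort$manifest$timestamp, "%Y-%m-%dT%H:%M:%OS3Z",
                       tz = "UTC"),
    sbp = cohort$manifest$sbp, dbp = cohort$manifest$dbp,
    hr = cohort$manifest$hr)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read sessions listed in a cohort manifest
#'
#' Loads every session the manifest points to, ordered by (subject,
#' timestamp). Malformed session files are collected into an error report
#' rather than silently dropped; an empty manifest yields an empty record
#' list with a warning.
#'
#' @param manifest_path Path to a manifest CSV written by [write_cohort()].
#' @return A list with `records` (list of [ppg_record()]) and `errors`
#'   (data frame of session_path, message).
#' @export
read_sessions <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!nrow(manifest)) {
    warning("empty manifest: no sessions to read")
    return(list(records = list(), errors = data.frame(
      session_path = character(0), message = character(0))))
  }
  base <- dirname(manifest_path)
  records <- list()
  errors <- list()
  for (i in seq_len(nrow(manifest))) {
    p <- file.path(base, manifest$session_path[i])
    rec <- tryCatch(read_session_csv(p), error = function(e) e)
    if (inherits(rec, "error")) {
      errors[[length(errors) + 1L]] <- data.frame(
        session_path = manifest$session_path[i],
        message = conditionMessage(rec))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  ord <- order(vapply(records, function(r) r$subject_id, character(1)),
               vapply(records, function(r) as.numeric(r$timestamp),
                      numeric(1)))
  list(records = records[ord],
       errors = if (length(errors)) do.call(rbind, errors) else data.frame(
         session_path = character(0), message = character(0)))
}

#' Save a fitted model as JSON
#'
#' Serializes `pls_model`, `gpr_model` or `lwpls_query` objects (scalars,
#' dimensions, numeric arrays at full precision) for reproducible evaluation
#' runs.
#'
#' @param model The fitted model object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  cls <- class(model)[1]
  if (!cls %in% c("pls_model", "gpr_model", "lwpls_query")) {
    stop("unsupported model class: ", cls, call. = FALSE)
  }
  payload <- lapply(unclass(model), function(f) {
    if (is.matrix(f)) list(dim = dim(f), data = as.numeric(f)) else f
  })
  jsonlite::write_json(list(class = cls, fields = payload), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON path.
#' @return The restored model object.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fields <- lapply(obj$fields, function(f) {
    if (is.list(f) && !is.null(f$dim)) {
      matrix(f$data, nrow = f$dim[1], ncol = f$dim[2])
    } else f
  })
  structure(fields, class = obj$class)
}
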