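#' Write a sensor recording as delimited text
#'
#' One row per sample: timestamp, the integer sEMG columns, three accelerometer
#' and three gyroscope columns. A small `#key=value` header declares the
#' channel layout, sampling rate and bit depth so that readers can validate
#' the stream. IMU values are stored with 5 decimal digits.
#'
#' @param rec `sensor_recording` object.
#' @param path Output file path (tab-separated text).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "sensor_recording"))
  n <- nrow(rec$semg)
  hdr <- c(sprintf("#subject_id=%s", rec$subject_id),
           sprintf("#sample_rate_hz=%s", format(rec$sample_rate_hz)),
           sprintf("#n_semg=%d", ncol(rec$semg)),
           sprintf("#semg_bits=%d", rec$semg_bits),
           sprintf("#t0=%s", format(rec$t0)))
  dt <- data.table::data.table(
    t = round((seq_len(n) - 1) / rec$sample_rate_hz, 6))
  for (j in seq_len(ncol(rec$semg))) dt[[paste0("semg", j)]] <- rec$semg[, j]
  im <- imu_channels()
  for (j in 1:3) dt[[im[j]]] <- round(rec$accel[, j], 5)
  for (j in 1:3) dt[[im[j + 3]]] <- round(rec$gyro[, j], 5)
  writeLines(hdr, path)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

read_header <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  hdr_lines <- grep("^#", lines, value = TRUE)
  if (length(lines) == 0L) stopf("'%s': empty file", path)
  kv <- strsplit(sub("^#", "", hdr_lines), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), ""),
                          vapply(kv, `[[`, "", 1))
  list(values = as.list(vals), n_header = length(hdr_lines))
}

#' Read a sensor recording written by [write_recording()]
#'
#' Rejects malformed input (missing header fields, wrong column count, ragged
#' rows, out-of-range sEMG integers) rather than truncating it. The round trip
#' write-then-read is lossless for the integer sEMG columns and preserves IMU
#' values to the stored precision.
#'
#' @param path Path to a recording file.
#' @return `sensor_recording` object.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stopf("'%s': no such file", path)
  h <- read_header(path)
  need <- c("subject_id", "sample_rate_hz", "n_semg", "semg_bits")
  miss <- setdiff(need, names(h$values))
  if (length(miss)) stopf("'%s': malformed header, missing %s", path,
                          paste(miss, collapse = ", "))
  n_semg <- as.integer(h$values$n_semg)
  bits <- as.integer(h$values$semg_bits)
  fs <- as.numeric(h$values$sample_rate_hz)
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", skip = h$n_header, header = TRUE,
                      fill = FALSE, data.table = TRUE),
    error = function(e) stopf("'%s': malformed data rows (%s)", path, conditionMessage(e)))
  expected <- c("t", semg_channels(n_semg), imu_channels())
  if (!identical(names(dt), expected)) {
    stopf("'%s': column layout %s does not match declared layout (%d sEMG + 6 IMU)",
          path, paste(names(dt), collapse = ","), n_semg)
  }
  if (nrow(dt) == 0L) stopf("'%s': no samples", path)
  semg <- as.matrix(dt[, semg_channels(n_semg), with = FALSE])
  if (any(semg != round(semg))) stopf("'%s': non-integer sEMG values", path)
  lim <- 2^(bits - 1)
  bad <- which(semg < -lim | semg > lim - 1)
  if (length(bad)) {
    stopf("'%s': sEMG value out of the %d-bit range at data line %d",
          path, bits, ((bad[1] - 1) %% nrow(semg)) + 1)
  }
  storage.mode(semg) <- "integer"
  sensor_recording(subject_id = h$values$subject_id, sample_rate_hz = fs,
                   semg = semg,
                   accel = as.matrix(dt[, imu_channels()[1:3], with = FALSE]),
                   gyro = as.matrix(dt[, imu_channels()[4:6], with = FALSE]),
                   semg_bits = bits,
                   t0 = as.numeric(h$values$t0 %||% 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an activity log
#'
#' Tab-separated rows `(activity, start_s, end_s)`, the dialect of a mobile
#' time-tracker export with timestamps as seconds from recording start.
#' Reading sorts events by start, rejects `end <= start` and overlapping
#' events, and warns about (but keeps) unknown activity classes, which label
#' non-smoking time.
#'
#' @param log `activity_log` object.
#' @param path File path.
#' @return `write_activity_log()`: `path` invisibly; `read_activity_log()`:
#'   an `activity_log` object.
#' @export
write_activity_log <- function(log, path) {
  data.table::fwrite(as.data.frame(log)[c("activity", "start_s", "end_s")],
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_activity_log
#' @export
read_activity_log <- function(path) {
  if (!file.exists(path)) stopf("'%s': no such file", path)
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", header = TRUE, fill = FALSE),
    error = function(e) stopf("'%s': malformed activity log (%s)", path,
                              conditionMessage(e)))
  if (!all(c("activity", "start_s", "end_s") %in% names(dt))) {
    stopf("'%s': activity log needs columns activity, start_s, end_s", path)
  }
  activity_log(as.data.frame(dt))
}

#' Write / read a dataset manifest
#'
#' JSON list of `(subject_id, recording, log)` path triples plus a format
#' version. Reading checks that subject ids are unique and that all referenced
#' files exist (paths are resolved relative to the manifest's directory).
#'
#' @param subjects Data frame with columns `subject_id`, `recording`, `log`.
#' @param path Manifest path.
#' @return `read_manifest()`: data frame of absolute paths with attribute
#'   `format_version`.
#' @export
write_manifest <- function(subjects, path) {
  stopifnot(all(c("subject_id", "recording", "log") %in% names(subjects)))
  jsonlite::write_json(list(format_version = "1.0", subjects = subjects),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("'%s': no such file", path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- m$subjects
  if (anyDuplicated(s$subject_id)) stopf("manifest has duplicate subject ids")
  base <- dirname(normalizePath(path))
  abspath <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  s$recording <- abspath(s$recording)
  s$log <- abspath(s$log)
  for (f in c(s$recording, s$log)) {
    if (!file.exists(f)) stopf("manifest refers to missing file '%s'", f)
  }
  attr(s, "format_version") <- m$format_version
  s
}

#' Persist a spectrogram set as a chunked binary container
#'
#' Values go to `<path>.bin` (doubles, native endianness) and a JSON sidecar
#' `<path>.json` records dimensions, channel names, window references and the
#' spectrogram configuration for provenance. Binary storage is used because a
#' full study's worth of window images is far too large for delimited text.
#'
#' @param spec `spectrogram_set` object (see [featurize()]).
#' @param path Base path (without extension).
#' @return Base path, invisibly.
#' @export
write_tensor_set <- function(spec, path) {
  stopifnot(inherits(spec, "spectrogram_set"))
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(spec$values), con, size = 8)
  meta <- list(dims = dim(spec$values), channels = spec$channels,
               windows = spec$windows, labels = spec$labels,
               config = unclass(spec$config))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_tensor_set
#' @export
read_tensor_set <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dims)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 8)
  if (length(v) != n) stopf("'%s.bin': truncated tensor container", path)
  cfg <- do.call(spectrogram_config, meta$config[names(meta$config) %in%
                                                   names(formals(spectrogram_config))])
  structure(list(values = array(v, dim = meta$dims), channels = meta$channels,
                 windows = as.data.frame(meta$windows),
                 labels = meta$labels, config = cfg),
            class = "spectrogram_set")
}

fmt_count <- function(x) formatC(x, big.mark = ",", format = "d")

#' Write an evaluation report
#'
#' Emits a machine-readable JSON report at `path` and a human-readable table
#' (one row per sensor configuration with TPs/FPs/FNs/TNs and accumulated
#' micro metrics, counts printed with thousands separators) at the same path
#' with extension `.txt`.
#'
#' @param result List of `evaluation_result` objects (see [run_experiment()]),
#'   or a single one.
#' @param path Output JSON path.
#' @return Invisible list of the two file paths.
#' @export
write_report <- function(result, path) {
  if (inherits(result, "evaluation_result")) result <- list(result)
  stopifnot(length(result) > 0L,
            all(vapply(result, inherits, TRUE, "evaluation_result")))
  rows <- lapply(result, function(r) {
    cm <- r$accumulated$confusion
    list(configuration = r$configuration,
         tp = cm["tp"], fp = cm["fp"], fn = cm["fn"], tn = cm["tn"],
         micro = as.list(r$accumulated$micro),
         macro = as.list(r$accumulated$macro),
         folds = lapply(r$folds, function(f) {
           list(subject_id = f$subject_id, confusion = as.list(f$confusion),
                metrics = as.list(f$metrics))
         }),
         paired = r$paired)
  })
  jsonlite::write_json(list(format_version = "1.0", results = unname(rows)),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  txt <- sub("\\.json$", "", path)
  txt <- paste0(txt, ".txt")
  header <- sprintf("%-28s %8s %8s %8s %8s %6s %6s %6s %6s",
                    "Configuration", "TPs", "FPs", "FNs", "TNs",
                    "Rec", "Prec", "F1", "Acc")
  lines <- vapply(result, function(r) {
    cm <- r$accumulated$confusion
    m <- r$accumulated$micro
    sprintf("%-28s %8s %8s %8s %8s %6.2f %6.2f %6.2f %6.2f",
            r$configuration, fmt_count(cm["tp"]), fmt_count(cm["fp"]),
            fmt_count(cm["fn"]), fmt_count(cm["tn"]),
            m["recall"], m["precision"], m["f1"], m["accuracy"])
  }, "")
  writeLines(c(header, lines), txt)
  invisible(list(json = path, table = txt))
}

#' @rdname write_report
#' @param json_path Path of a report written by `write_report()`.
#' @export
read_report <- function(json_path) {
  jsonlite::read_json(json_path, simplifyVector = TRUE)
}
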