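test_that("recordings round-trip losslessly through delimited text", {
  s <- fixture_subject()
  rec <- s$recording
  path <- tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$semg, rec$semg)
  expect_lt(max(abs(back$accel - rec$accel)), 1e-5 + 1e-9)
  expect_lt(max(abs(back$gyro - rec$gyro)), 1e-5 + 1e-9)
  expect_equal(back$subject_id, rec$subject_id)
  expect_equal(back$sample_rate_hz, rec$sample_rate_hz)
})

test_that("malformed recording files are rejected with informative errors", {
  s <- fixture_subject()
  path <- tempfile(fileext = ".tsv")
  write_recording(s$recording, path)

  # declared 8 sEMG columns but one missing
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  tab_split <- strsplit(lines[!hdr], "\t")
  drop7 <- vapply(tab_split, function(x) paste(x[-3], collapse = "\t"), "")
  p2 <- tempfile(); writeLines(c(lines[hdr], drop7), p2)
  expect_error(read_recording(p2), "layout")

  # empty file is an error, not an empty recording
  p3 <- tempfile(); file.create(p3)
  expect_error(read_recording(p3), "empty|header|missing")

  # header without declared layout
  p4 <- tempfile(); writeLines(c("#subject_id=S01", lines[!hdr]), p4)
  expect_error(read_recording(p4), "missing")

  # out-of-range sEMG value
  body <- lines[!hdr]
  f <- strsplit(body[2], "\t")[[1]]; f[2] <- "300"
  p5 <- tempfile(); writeLines(c(lines[hdr], body[1], paste(f, collapse = "\t"), body[-(1:2)]), p5)
  expect_error(read_recording(p5), "range")
  expect_error(read_recording(tempfile()), "no such file")
})

test_that("activity logs parse, sort, and reject impossible events", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(activity = c("eating", "reading", "smoking_sitting"),
                   start_s = c(500, 0, 200), end_s = c(700, 100, 400))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  log <- read_activity_log(path)
  expect_equal(log$activity, c("reading", "smoking_sitting", "eating"))

  # the ten protocol activities are all known classes
  p1 <- tempfile()
  ten <- data.frame(activity = activity_classes(),
                    start_s = seq(0, 900, by = 100),
                    end_s = seq(100, 1000, by = 100))
  write.table(ten, p1, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_silent(l10 <- read_activity_log(p1))
  expect_equal(nrow(l10), 10L)

  # end <= start
  p2 <- tempfile()
  write.table(data.frame(activity = "reading", start_s = 10, end_s = 5),
              p2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_activity_log(p2), "end <= start")

  # overlap
  p3 <- tempfile()
  write.table(data.frame(activity = c("reading", "eating"),
                         start_s = c(0, 50), end_s = c(100, 150)),
              p3, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_activity_log(p3), "overlap")

  # unknown class passes through with a warning
  p4 <- tempfile()
  write.table(data.frame(activity = "juggling", start_s = 0, end_s = 10),
              p4, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_warning(lg <- read_activity_log(p4), "unknown")
  expect_equal(lg$activity, "juggling")
})

test_that("manifests validate subject uniqueness and file existence", {
  dir <- tempfile(); dir.create(dir)
  s <- fixture_subject()
  write_recording(s$recording, file.path(dir, "r.tsv"))
  write_activity_log(s$log, file.path(dir, "l.tsv"))
  mpath <- file.path(dir, "manifest.json")
  write_manifest(data.frame(subject_id = "S01", recording = "r.tsv", log = "l.tsv"),
                 mpath)
  m <- read_manifest(mpath)
  expect_equal(m$subject_id, "S01")
  expect_true(file.exists(m$recording))

  write_manifest(data.frame(subject_id = "S01", recording = "r.tsv",
                            log = "missing.tsv"), mpath)
  expect_error(read_manifest(mpath), "missing")
})

test_that("evaluation reports render counts with thousands separators and re-parse", {
  cm <- smokescreen:::as_confusion(5091, 697, 1135, 11574)
  fake <- structure(list(
    configuration = "fused",
    channels = "x",
    folds = list(list(subject_id = "S01", confusion = cm, metrics = metrics(cm))),
    accumulated = list(confusion = cm, micro = metrics(cm),
                       macro = unclass(metrics(cm))),
    predictions = NULL, paired = NULL), class = "evaluation_result")
  path <- tempfile(fileext = ".json")
  out <- write_report(fake, path)
  txt <- readLines(out$table)
  expect_length(txt, 2L)   # header + one data row
  expect_match(txt[2], "11,574")
  expect_match(txt[2], "5,091")

  back <- read_report(path)
  expect_equal(back$results$tp, 5091)
  expect_equal(back$results$micro$precision, metrics(cm)[["precision"]],
               tolerance = 1e-12)
})

test_that("tensor containers round-trip values, labels and provenance", {
  s <- fixture_subject()
  ws <- label_windows(segment(s$recording), s$log)[1:6, ]
  fs <- featurize(ws, s$recording, c("semg1", "gyro_x"),
                  reduced_spectrogram_config())
  base <- tempfile()
  write_tensor_set(fs, base)
  back <- read_tensor_set(base)
  expect_equal(back$values, fs$values, tolerance = 0)
  expect_equal(back$channels, fs$channels)
  expect_equal(back$labels, fs$labels)
  expect_equal(back$config$n_fft, fs$config$n_fft)
})
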