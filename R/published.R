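#' Reference confusion counts of the original validation study
#'
#' Accumulated LOSO confusion counts and the rounded metrics reported by the
#' original 16-subject armband validation study, one row per sensor
#' configuration. These serve as worked examples for the metric arithmetic;
#' the underlying recordings were never deposited, so the counts are inputs,
#' not something this package can regenerate.
#'
#' @return Data frame with columns `configuration`, `tp`, `fp`, `fn`, `tn`
#'   and the printed `rec`, `prec`, `f1`, `acc` values.
#' @export
reference_confusion_counts <- function() {
  data.frame(
    configuration = c("semg_all", "semg_selected", "imu", "fused"),
    tp = c(4329L, 4711L, 4765L, 5091L),
    fp = c(1312L, 1294L, 854L, 697L),
    fn = c(1897L, 1515L, 1351L, 1135L),
    tn = c(10959L, 10977L, 11292L, 11574L),
    rec = c(0.69, 0.75, 0.79, 0.82),
    prec = c(0.76, 0.78, 0.85, 0.88),
    f1 = c(0.70, 0.75, 0.81, 0.84),
    acc = c(0.82, 0.84, 0.87, 0.90),
    stringsAsFactors = FALSE
  )
}

#' Recompute metrics from the reference confusion counts
#'
#' For every configuration row of [reference_confusion_counts()], recomputes
#' recall, precision, F1 and accuracy from the accumulated counts (the micro
#' convention) and compares them, at two decimals, with the printed values.
#' Some printed values do not match their own accumulated counts (they appear
#' to follow a different averaging convention); those rows are flagged as
#' mismatches rather than forced.
#'
#' @param quiet Suppress the printed table.
#' @return Data frame with computed and printed values plus per-metric
#'   `match_*` flags, invisibly when printed.
#' @export
check_published_metrics <- function(quiet = FALSE) {
  ref <- reference_confusion_counts()
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    m <- metrics(as_confusion(ref$tp[i], ref$fp[i], ref$fn[i], ref$tn[i]))
    data.frame(configuration = ref$configuration[i],
               rec_computed = round(m[["recall"]], 2),
               prec_computed = round(m[["precision"]], 2),
               f1_computed = round(m[["f1"]], 2),
               acc_computed = round(m[["accuracy"]], 2),
               rec_printed = ref$rec[i], prec_printed = ref$prec[i],
               f1_printed = ref$f1[i], acc_printed = ref$acc[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  for (m in c("rec", "prec", "f1", "acc")) {
    out[[paste0("match_", m)]] <-
      abs(out[[paste0(m, "_computed")]] - out[[paste0(m, "_printed")]]) < 0.005
  }
  if (!quiet) {
    for (i in seq_len(nrow(out))) {
      cat(sprintf("%-14s", out$configuration[i]))
      for (m in c("rec", "prec", "f1", "acc")) {
        cat(sprintf("  %s %.2f/%.2f %s", m, out[[paste0(m, "_computed")]][i],
                    out[[paste0(m, "_printed")]][i],
                    if (out[[paste0("match_", m)]][i]) "ok" else "MISMATCH"))
      }
      cat("\n")
    }
  }
  invisible(out)
}
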