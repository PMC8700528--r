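#' Measure every annotation in a directory
#'
#' Reads each `*.json` LabelMe annotation in `dir`, computes the calibration
#' and the five morphometric measurements, and returns one row per stageable
#' record. Records that fail to parse or are not stageable are skipped with
#' a message, never a hard failure: batch runs must survive stray files.
#'
#' @param dir directory of LabelMe `.json` files.
#' @param out_csv optional path; the table is also written there.
#' @return Data frame with columns `image_id`, `c2conc_mm`, `c3conc_mm`,
#'   `c4conc_mm`, `c3bar`, `c4bar` plus a `skipped` attribute naming skipped
#'   files.
#' @export
measure_directory <- function(dir, out_csv = NULL) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  rows <- list()
  skipped <- character(0)
  for (f in files) {
    row <- tryCatch({
      rec <- suppressWarnings(read_labelme(f))
      if (!is_stageable(rec)) stop("not stageable")
      m <- measure_landmarks(rec)
      data.frame(image_id = rec$image_id,
                 c2conc_mm = m[["c2conc"]], c3conc_mm = m[["c3conc"]],
                 c4conc_mm = m[["c4conc"]], c3bar = m[["c3bar"]],
                 c4bar = m[["c4bar"]], stringsAsFactors = FALSE)
    }, error = function(e) {
      message("skipping ", basename(f), ": ", conditionMessage(e))
      NULL
    })
    if (is.null(row)) skipped <- c(skipped, basename(f)) else
      rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(image_id = character(), c2conc_mm = numeric(),
               c3conc_mm = numeric(), c4conc_mm = numeric(),
               c3bar = numeric(), c4bar = numeric())
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Stage every annotation in a directory
#'
#' As [measure_directory()], continuing through the staging workflow.
#'
#' @param dir directory of LabelMe `.json` files.
#' @param thresholds a [cvm_thresholds()] or a YAML config path (see
#'   [read_thresholds()]).
#' @param out_csv optional output CSV path.
#' @return Data frame with columns `image_id`, `stage`, concavity/shape
#'   flags and `pattern_consistent`; `skipped` attribute as above.
#' @export
stage_directory <- function(dir, thresholds = cvm_thresholds(),
                            out_csv = NULL) {
  if (is.character(thresholds)) thresholds <- read_thresholds(thresholds)
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  rows <- list()
  skipped <- character(0)
  for (f in files) {
    row <- tryCatch({
      rec <- suppressWarnings(read_labelme(f))
      s <- stage_record(rec, thresholds)
      data.frame(image_id = rec$image_id, stage = as.character(s$stage),
                 concave_c2 = s$concave_c2, concave_c3 = s$concave_c3,
                 concave_c4 = s$concave_c4,
                 c3_shape = as.character(s$c3_shape),
                 c4_shape = as.character(s$c4_shape),
                 pattern_consistent = s$pattern_consistent,
                 gold_stage = if (is.null(rec$gold_stage)) NA_character_
                              else rec$gold_stage,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      message("skipping ", basename(f), ": ", conditionMessage(e))
      NULL
    })
    if (is.null(row)) skipped <- c(skipped, basename(f)) else
      rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(image_id = character(), stage = character())
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Evaluate predicted against gold stages from CSV files
#'
#' Each CSV needs columns `image_id` and `stage`; rows are paired by
#' `image_id` (a mismatch is an error).
#'
#' @param pred_csv,gold_csv file paths (or data frames).
#' @param out_json optional path for a JSON report mirroring the per-stage
#'   metric table.
#' @return A `cvm_metric_report`.
#' @export
evaluate_staging_files <- function(pred_csv, gold_csv, out_json = NULL) {
  pred <- if (is.data.frame(pred_csv)) pred_csv else
    utils::read.csv(pred_csv, stringsAsFactors = FALSE)
  gold <- if (is.data.frame(gold_csv)) gold_csv else
    utils::read.csv(gold_csv, stringsAsFactors = FALSE)
  for (df in list(pred, gold)) {
    if (!all(c("image_id", "stage") %in% names(df))) {
      stop("CSV must have columns image_id and stage")
    }
  }
  if (!setequal(pred$image_id, gold$image_id) ||
      anyDuplicated(pred$image_id) || anyDuplicated(gold$image_id)) {
    stop("pairing error: image_ids do not match one-to-one")
  }
  pred <- pred[match(gold$image_id, pred$image_id), ]
  rep <- metric_report(gold$stage, pred$stage)
  if (!is.null(out_json)) {
    jsonlite::write_json(
      list(per_class = rep$per_class, accuracy = rep$accuracy,
           kappa = rep$kappa, icc = rep$icc),
      out_json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  rep
}
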