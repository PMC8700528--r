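#' Stage confusion matrix
#'
#' Cross-tabulates gold-standard and predicted stages into a 6 x 6 count
#' matrix (rows = gold, columns = predicted).
#'
#' @param gold,pred vectors of stage labels (`"CS1"`..`"CS6"`), equal length,
#'   non-empty.
#' @return An object of class `cvm_confusion` (integer matrix).
#' @export
confusion_matrix <- function(gold, pred) {
  if (length(gold) != length(pred)) stop("gold and pred differ in length")
  if (length(gold) == 0) stop("empty stage vectors")
  tab <- table(gold = as_stage(gold), pred = as_stage(pred))
  structure(unclass(tab), class = "cvm_confusion")
}

#' @export
print.cvm_confusion <- function(x, ...) {
  cat("<cvm_confusion> rows = gold, columns = predicted, n =", sum(x), "\n")
  print(unclass(x))
  invisible(x)
}

#' Build a confusion matrix directly from counts
#'
#' @param counts 6 x 6 non-negative matrix, rows = gold, columns = predicted.
#' @return A `cvm_confusion` object.
#' @export
as_confusion <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 6, ncol(counts) == 6, all(counts >= 0))
  dimnames(counts) <- list(gold = stage_levels(), pred = stage_levels())
  structure(counts, class = "cvm_confusion")
}

#' Per-stage one-vs-rest classification metrics
#'
#' For each stage treated as the positive class: `TP` is the diagonal count,
#' `FN` the rest of its gold row, `FP` the rest of its predicted column and
#' `TN` the remainder. Then precision = TP/(TP+FP) (positive predictive
#' value), recall = TP/(TP+FN) (sensitivity), specificity = TN/(TN+FP), and
#' F1 the harmonic mean of precision and recall. A zero denominator yields
#' `NA` (an explicit undefined marker), never a silent 0.
#'
#' @param cm a `cvm_confusion`.
#' @param class optional single stage label; when omitted all six stages are
#'   returned as a data frame.
#' @return Data frame with columns `stage`, `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `specificity`, `f1`.
#' @export
per_class_metrics <- function(cm, class = NULL) {
  cm <- unclass(cm)
  total <- sum(cm)
  classes <- if (is.null(class)) stage_levels() else as.character(class)
  rows <- lapply(classes, function(cl) {
    i <- match(cl, stage_levels())
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    data.frame(stage = cl, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = safe_div(tp, tp + fp),
               recall = safe_div(tp, tp + fn),
               specificity = safe_div(tn, tn + fp),
               f1 = f1_from_pr(safe_div(tp, tp + fp), safe_div(tp, tp + fn)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' F1 score from precision and recall
#'
#' Harmonic mean `2 * p * r / (p + r)`; `NA` (undefined) when both are zero
#' or either is `NA`.
#'
#' @param precision,recall fractions in `[0, 1]`.
#' @return F1 in `[0, 1]` or `NA`.
#' @export
f1_from_pr <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision == 0 && recall == 0) return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' Overall staging accuracy
#'
#' @param cm a `cvm_confusion` with at least one count.
#' @return Fraction of exactly matching stages (trace / total).
#' @export
overall_accuracy <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(cm)) / total
}

#' Cohen's kappa
#'
#' Unweighted chance-corrected agreement
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = trace/total` and chance agreement
#' `p_e = sum(row_i * col_i) / total^2`.
#'
#' @param cm a square count matrix (`cvm_confusion` or plain matrix).
#' @return Kappa in `[-1, 1]`; `NA` when `p_e = 1` (no possible
#'   disagreement structure).
#' @export
cohen_kappa <- function(cm) {
  cm <- unclass(as.matrix(cm))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (pe >= 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Intraclass correlation coefficient
#'
#' Agreement between numeric ratings of `n` subjects by `k` raters, from the
#' two-way ANOVA mean squares (rows = subjects, columns = raters). The
#' default `ICC2` is the two-way random-effects, absolute-agreement,
#' single-rater coefficient ICC(2,1) — the natural choice when one "rater"
#' is an algorithm compared against a gold standard and systematic offsets
#' should count against agreement. `ICC3` is the consistency variant
#' ICC(3,1); `ICC2k` the average-rater absolute-agreement ICC(2,k).
#'
#' Ordinal stages are coded as equally spaced integers (CS1..CS6 -> 1..6)
#' by [stage_icc()].
#'
#' @param ratings numeric matrix, `n` subjects x `k` raters, no missing
#'   cells, `n >= 2`, `k >= 2`.
#' @param type one of `"ICC2"`, `"ICC3"`, `"ICC2k"`.
#' @return ICC value; `NA` when all ratings are constant (zero variance).
#' @export
icc <- function(ratings, type = c("ICC2", "ICC3", "ICC2k")) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  if (anyNA(ratings)) stop("missing cells are not supported")
  if (stats::var(as.vector(ratings)) == 0) return(NA_real_)
  df <- data.frame(y = as.vector(ratings),
                   subject = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  a <- suppressWarnings(stats::anova(stats::aov(y ~ subject + rater,
                                                data = df)))
  msr <- a["subject", "Mean Sq"]   # between-subject
  msc <- a["rater", "Mean Sq"]     # between-rater
  mse <- a["Residuals", "Mean Sq"] # residual
  switch(type,
    ICC2  = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    ICC3  = (msr - mse) / (msr + (k - 1) * mse),
    ICC2k = (msr - mse) / (msr + (msc - mse) / n))
}

#' ICC between two stage assignments
#'
#' @param gold,pred stage label vectors of equal length.
#' @param type passed to [icc()].
#' @return ICC treating stages as equally spaced integer codes.
#' @export
stage_icc <- function(gold, pred, type = "ICC2") {
  icc(cbind(as.integer(as_stage(gold)), as.integer(as_stage(pred))),
      type = type)
}

#' Full staging metric report
#'
#' @param gold,pred stage label vectors of equal length.
#' @param icc_type passed to [icc()].
#' @return An object of class `cvm_metric_report`: confusion matrix,
#'   per-class metrics, overall accuracy, Cohen's kappa and ICC.
#' @export
metric_report <- function(gold, pred, icc_type = "ICC2") {
  cm <- confusion_matrix(gold, pred)
  structure(
    list(confusion = cm,
         per_class = per_class_metrics(cm),
         accuracy = overall_accuracy(cm),
         kappa = cohen_kappa(cm),
         icc = stage_icc(gold, pred, type = icc_type)),
    class = "cvm_metric_report")
}

#' Metric report from a prebuilt confusion matrix
#'
#' As [metric_report()] but starting from counts; the ICC is computed from
#' the stage pairs implied by the counts.
#'
#' @param cm a `cvm_confusion`.
#' @param icc_type passed to [icc()].
#' @return A `cvm_metric_report`.
#' @export
metric_report_from_confusion <- function(cm, icc_type = "ICC2") {
  pairs <- expand_confusion(cm)
  metric_report(pairs$gold, pairs$pred, icc_type = icc_type)
}

# expand a count matrix back to one (gold, pred) pair per scored image
expand_confusion <- function(cm) {
  cm <- unclass(as.matrix(cm))
  idx <- which(cm > 0, arr.ind = TRUE)
  gold <- rep(stage_levels()[idx[, 1]], times = cm[idx])
  pred <- rep(stage_levels()[idx[, 2]], times = cm[idx])
  list(gold = gold, pred = pred)
}

#' @export
print.cvm_metric_report <- function(x, digits = 2, ...) {
  cat("<cvm_metric_report>\n")
  pc <- x$per_class
  pc[, c("precision", "recall", "specificity", "f1")] <-
    lapply(pc[, c("precision", "recall", "specificity", "f1")],
           round_half_up, digits = digits)
  print(pc, row.names = FALSE)
  cat(sprintf("accuracy %.2f  kappa %.2f  ICC %.2f\n",
              x$accuracy, x$kappa, x$icc))
  invisible(x)
}

#' Round half away from zero
#'
#' Display rounding used in the report tables (so 0.845 prints as 0.85),
#' unlike base `round()`'s round-half-even. Full precision is always kept
#' internally.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Reconstruct per-stage confusion counts from published summaries
#'
#' Given per-stage gold counts `n` and printed precision/recall, recover the
#' integer one-vs-rest counts: `TP = round(recall * n)`,
#' `FP = round(TP / precision) - TP`, `FN = n - TP`,
#' `TN = total - TP - FP - FN`. Also assembles a full 6 x 6 matrix with
#' those margins (off-diagonal mass placed by a greedy transport fill) so the
#' whole evaluation suite can be re-run on it; its diagonal and margins are
#' exact, the placement of individual confusions is not unique.
#'
#' @param n integer vector of per-stage gold counts (length 6).
#' @param precision,recall numeric vectors of per-stage values (length 6).
#' @return List with `counts` (data frame of per-stage TP/FP/FN/TN) and
#'   `confusion` (a `cvm_confusion` with matching margins).
#' @export
confusion_from_metrics <- function(n, precision, recall) {
  stopifnot(length(n) == 6, length(precision) == 6, length(recall) == 6)
  total <- sum(n)
  tp <- round(recall * n)
  fp <- ifelse(tp > 0, round(tp / precision) - tp, 0)
  fn <- n - tp
  tn <- total - tp - fp - fn
  counts <- data.frame(stage = stage_levels(), n = n, tp = tp, fp = fp,
                       fn = fn, tn = tn)
  if (sum(fp) != sum(fn)) {
    stop("inconsistent published summaries: total FP ", sum(fp),
         " != total FN ", sum(fn))
  }
  cm <- diag(tp)
  need_row <- fn  # off-diagonal mass per gold row
  need_col <- fp  # off-diagonal mass per predicted column
  for (i in 1:6) for (j in 1:6) {
    if (i == j) next
    put <- min(need_row[i], need_col[j])
    cm[i, j] <- put
    need_row[i] <- need_row[i] - put
    need_col[j] <- need_col[j] - put
  }
  list(counts = counts, confusion = as_confusion(cm))
}

#' Landmark placement error report
#'
#' Pairs predicted and reference annotations by `image_id`, converts each
#' per-landmark Euclidean displacement to millimetres using the reference
#' record's calibration, and summarises per landmark across images (mean and
#' sample SD). The `Total` row follows the per-landmark convention: the
#' unweighted mean of the 13 per-landmark means, and the sample SD (n-1) of
#' those 13 means. Set `pooled = TRUE` for image-weighted pooling of all
#' distances instead.
#'
#' @param pred,truth lists of [annotation_record()]s sharing `image_id`s.
#' @param pooled logical; use pooled mean/SD over all distances for the
#'   totals instead of the per-landmark-mean convention.
#' @return An object of class `cvm_landmark_errors`: data frame `per_landmark`
#'   (`landmark`, `mean_mm`, `sd_mm`), `total_mean`, `total_sd`, and the raw
#'   `distances` matrix (images x landmarks, mm).
#' @export
landmark_errors <- function(pred, truth, pooled = FALSE) {
  ids_p <- vapply(pred, function(r) r$image_id, character(1))
  ids_t <- vapply(truth, function(r) r$image_id, character(1))
  if (!setequal(ids_p, ids_t) || anyDuplicated(ids_p) || anyDuplicated(ids_t)) {
    stop("pairing error: pred and truth image_ids do not match one-to-one")
  }
  pred <- pred[match(ids_t, ids_p)]
  nms <- anatomic_landmark_names()
  d <- t(vapply(seq_along(truth), function(i) {
    sc <- as.numeric(compute_scale(truth[[i]]))
    pt <- get_points(truth[[i]], nms)
    pp <- get_points(pred[[i]], nms)
    sqrt(rowSums((pt - pp)^2)) * sc
  }, numeric(length(nms))))
  colnames(d) <- nms
  rownames(d) <- ids_t
  per <- data.frame(
    landmark = nms,
    mean_mm = colMeans(d),
    sd_mm = apply(d, 2, function(v) if (length(v) > 1) stats::sd(v) else NA_real_),
    row.names = NULL, stringsAsFactors = FALSE)
  tot <- summarize_landmark_means(per$mean_mm)
  if (pooled) tot <- list(total_mean = mean(d), total_sd = stats::sd(as.vector(d)))
  structure(list(per_landmark = per, total_mean = tot$total_mean,
                 total_sd = tot$total_sd, distances = d),
            class = "cvm_landmark_errors")
}

#' Total-row summary of per-landmark mean errors
#'
#' The report convention for the `Total` row: unweighted mean of the
#' per-landmark mean errors, and the sample standard deviation (n-1 across
#' landmarks) of those means.
#'
#' @param means numeric vector of per-landmark mean errors (mm).
#' @return List with `total_mean` and `total_sd`.
#' @export
summarize_landmark_means <- function(means) {
  list(total_mean = mean(means), total_sd = stats::sd(means))
}

#' @export
print.cvm_landmark_errors <- function(x, digits = 2, ...) {
  cat("<cvm_landmark_errors> over", nrow(x$distances), "images\n")
  per <- x$per_landmark
  per$mean_mm <- round_half_up(per$mean_mm, digits)
  per$sd_mm <- round_half_up(per$sd_mm, digits)
  print(per, row.names = FALSE)
  cat(sprintf("Total: %.2f +/- %.2f mm\n",
              round_half_up(x$total_mean, digits),
              round_half_up(x$total_sd, digits)))
  invisible(x)
}

#' Export a metric report as a data frame / CSV
#'
#' @param x a `cvm_metric_report`.
#' @param ... unused.
#' @return Data frame mirroring the per-stage report layout with the overall
#'   accuracy, kappa and ICC attached as attributes.
#' @export
as.data.frame.cvm_metric_report <- function(x, ...) {
  df <- x$per_class
  attr(df, "accuracy") <- x$accuracy
  attr(df, "kappa") <- x$kappa
  attr(df, "icc") <- x$icc
  df
}
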