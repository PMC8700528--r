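#' Staging thresholds
#'
#' The decision workflow maps the five morphometric quantities to a stage
#' through three thresholds: the minimum concavity depth at which a lower
#' border counts as concave, and the two BAR cut points separating
#' horizontal-rectangle, square and vertical-rectangle body shapes. Boundary
#' ties are inclusive on the mature side (a depth exactly at the threshold
#' counts as concave; a BAR exactly at a cut point takes the more mature
#' shape class).
#'
#' Defaults: concavity 1.0 mm (the conventional visibility criterion for a
#' lower-border concavity); square band BAR in (0.95, 1.2]; vertical at or
#' below 0.95. These are engineering defaults, all overridable, since the
#' original Baccetti cut points are not published as numbers.
#'
#' @param concavity_mm minimum concavity depth (mm) counted as concave.
#' @param square_upper_bar BAR at or below which a body is square (or more
#'   mature) rather than horizontal.
#' @param vertical_upper_bar BAR at or below which a body is a vertical
#'   rectangle.
#' @return An object of class `cvm_thresholds`.
#' @export
cvm_thresholds <- function(concavity_mm = 1.0, square_upper_bar = 1.2,
                           vertical_upper_bar = 0.95) {
  if (!(concavity_mm > 0)) stop("concavity_mm must be positive")
  if (!(vertical_upper_bar > 0 && vertical_upper_bar < square_upper_bar)) {
    stop("need 0 < vertical_upper_bar < square_upper_bar")
  }
  structure(list(concavity_mm = concavity_mm,
                 square_upper_bar = square_upper_bar,
                 vertical_upper_bar = vertical_upper_bar),
            class = "cvm_thresholds")
}

#' @export
print.cvm_thresholds <- function(x, ...) {
  cat(sprintf(paste0("<cvm_thresholds> concave >= %.3g mm; ",
                     "vertical <= %.3g < square <= %.3g < horizontal\n"),
              x$concavity_mm, x$vertical_upper_bar, x$square_upper_bar))
  invisible(x)
}

#' Read staging thresholds from a YAML config file
#'
#' Recognised keys: `concavity_mm`, `square_upper_bar`, `vertical_upper_bar`;
#' missing keys fall back to the defaults of [cvm_thresholds()].
#'
#' @param path YAML file path; when the file does not exist the defaults are
#'   returned with a message.
#' @return A [cvm_thresholds()] object.
#' @export
read_thresholds <- function(path) {
  if (is.null(path) || !file.exists(path)) {
    if (!is.null(path)) message("thresholds file not found; using defaults")
    return(cvm_thresholds())
  }
  cfg <- yaml::read_yaml(path)
  defaults <- cvm_thresholds()
  cvm_thresholds(
    concavity_mm = cfg$concavity_mm %||% defaults$concavity_mm,
    square_upper_bar = cfg$square_upper_bar %||% defaults$square_upper_bar,
    vertical_upper_bar = cfg$vertical_upper_bar %||% defaults$vertical_upper_bar)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Is a lower border concave?
#'
#' @param conc concavity depth in mm (non-negative); vectorised.
#' @param thresholds a [cvm_thresholds()].
#' @return Logical: depth at or above the concavity threshold.
#' @export
detect_concavity <- function(conc, thresholds = cvm_thresholds()) {
  stopifnot(all(conc >= 0))
  conc >= thresholds$concavity_mm
}

#' Classify a vertebral body shape from its BAR
#'
#' @param bar base-to-anterior-height ratio (positive); vectorised.
#' @param thresholds a [cvm_thresholds()].
#' @return Factor with levels `horizontal`, `square`, `vertical` (ordered by
#'   maturity, vertical most mature). `horizontal` covers both the trapezoid
#'   of early stages and the horizontal rectangle: with only the BAR
#'   available the two are indistinguishable.
#' @export
classify_shape <- function(bar, thresholds = cvm_thresholds()) {
  if (any(bar <= 0)) stop("BAR must be positive")
  out <- ifelse(bar <= thresholds$vertical_upper_bar, "vertical",
                ifelse(bar <= thresholds$square_upper_bar, "square",
                       "horizontal"))
  factor(out, levels = c("horizontal", "square", "vertical"), ordered = TRUE)
}

#' Assign a CVM stage from the five measurements
#'
#' The decision workflow counts concave lower borders among C2, C3, C4:
#' 0 concave is CS1, 1 is CS2, 2 is CS3. With all three concave the stage is
#' decided by the C3/C4 body shapes — CS6 if at least one body is a vertical
#' rectangle, else CS5 if at least one is square, else CS4 (the most mature
#' shape present wins).
#'
#' Staging is by the *number* of concave borders, not their identity, so the
#' decision is total even for anatomically out-of-order patterns that can
#' arise under landmark noise (e.g. C3 concave while C2 flat). Such patterns
#' are flagged with `pattern_consistent = FALSE`: concavity normally appears
#' in superior-to-inferior order, C2 first, so the concave set should be a
#' prefix of (C2, C3, C4).
#'
#' @param measurements a `cvm_measurements` object (see
#'   [measure_landmarks()], [measurement_set()]).
#' @param thresholds a [cvm_thresholds()].
#' @return An object of class `cvm_staging`: list with `stage` (ordered
#'   factor), concavity flags, shape classes and `pattern_consistent`.
#' @export
cvm_stage <- function(measurements, thresholds = cvm_thresholds()) {
  conc <- as.numeric(measurements[c("c2conc", "c3conc", "c4conc")])
  concave <- detect_concavity(conc, thresholds)
  c3_shape <- classify_shape(measurements[["c3bar"]], thresholds)
  c4_shape <- classify_shape(measurements[["c4bar"]], thresholds)
  k <- sum(concave)
  stage <- if (k < 3) {
    stage_levels()[k + 1]
  } else {
    shapes <- c(as.character(c3_shape), as.character(c4_shape))
    if ("vertical" %in% shapes) "CS6"
    else if ("square" %in% shapes) "CS5"
    else "CS4"
  }
  consistent <- identical(concave, c(rep(TRUE, k), rep(FALSE, 3 - k)))
  structure(
    list(stage = as_stage(stage),
         concave_c2 = concave[1], concave_c3 = concave[2],
         concave_c4 = concave[3],
         c3_shape = c3_shape, c4_shape = c4_shape,
         pattern_consistent = consistent,
         measurements = measurements),
    class = "cvm_staging")
}

#' @export
print.cvm_staging <- function(x, ...) {
  cat("<cvm_staging>", as.character(x$stage),
      if (!x$pattern_consistent) "(atypical concavity pattern)" else "", "\n")
  cat(sprintf("  concave: C2 %s, C3 %s, C4 %s; shapes: C3 %s, C4 %s\n",
              x$concave_c2, x$concave_c3, x$concave_c4,
              as.character(x$c3_shape), as.character(x$c4_shape)))
  invisible(x)
}

#' Stage an annotation record end to end
#'
#' Composition of [compute_scale()], [measure_landmarks()] and
#' [cvm_stage()].
#'
#' @param record a stageable [annotation_record()].
#' @param thresholds a [cvm_thresholds()].
#' @return A `cvm_staging` object.
#' @export
stage_record <- function(record, thresholds = cvm_thresholds()) {
  scale <- compute_scale(record)
  cvm_stage(measure_landmarks(record, scale), thresholds)
}
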