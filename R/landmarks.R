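#' Landmark vocabulary
#'
#' The fixed set of 15 landmark names used throughout the package: two
#' reference points (`R1`, `R2`) marking a 10 mm calibration segment, and 13
#' anatomic points on the second to fourth cervical vertebrae. Naming follows
#' the Baccetti CVM convention: `lp`/`la` are the posterior/anterior corners of
#' a lower border, `up`/`ua` the posterior/anterior corners of an upper border,
#' and `m` the deepest point of a lower-border concavity.
#'
#' @return Character vector of valid landmark names, in canonical order.
#' @export
landmark_names <- function() {
  c("R1", "R2",
    "C2lp", "C2m", "C2la",
    "C3up", "C3ua", "C3lp", "C3m", "C3la",
    "C4up", "C4ua", "C4lp", "C4m", "C4la")
}

#' @rdname landmark_names
#' @export
anatomic_landmark_names <- function() {
  setdiff(landmark_names(), c("R1", "R2"))
}

#' Maturation stage levels
#'
#' The six ordered cervical-vertebral-maturation stages. CS1 is pre-pubertal
#' (flat lower borders, trapezoid bodies), CS3 marks the pubertal growth
#' spurt, CS6 skeletal maturity.
#'
#' @return Character vector `c("CS1", ..., "CS6")`.
#' @export
stage_levels <- function() paste0("CS", 1:6)

as_stage <- function(x) {
  f <- factor(as.character(x), levels = stage_levels(), ordered = TRUE)
  if (anyNA(f) && !anyNA(x)) {
    bad <- setdiff(unique(as.character(x)), stage_levels())
    stop("invalid CVM stage label(s): ", paste(bad, collapse = ", "))
  }
  f
}

#' Construct an annotation record
#'
#' An annotation record holds one image's named landmarks in pixel
#' coordinates (0-based, origin at the top-left corner, y increasing
#' downward), together with optional image size, gold-standard stage and
#' rater id. A record is *stageable* when it carries `R1`, `R2` and all 13
#' anatomic landmarks.
#'
#' @param landmarks data frame with columns `name`, `x`, `y` (pixels), or a
#'   named list of length-2 numeric vectors.
#' @param image_id character identifier of the image.
#' @param image_width,image_height optional image extent in pixels.
#' @param gold_stage optional gold-standard stage label (`"CS1"`..`"CS6"`).
#' @param rater_id optional rater identifier.
#' @return An object of class `cvm_annotation`.
#' @export
annotation_record <- function(landmarks, image_id = "unknown",
                              image_width = NULL, image_height = NULL,
                              gold_stage = NULL, rater_id = NULL) {
  if (is.list(landmarks) && !is.data.frame(landmarks)) {
    landmarks <- data.frame(
      name = names(landmarks),
      x = vapply(landmarks, function(p) p[[1]], numeric(1)),
      y = vapply(landmarks, function(p) p[[2]], numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(landmarks), all(c("name", "x", "y") %in% names(landmarks)))
  landmarks$name <- as.character(landmarks$name)
  landmarks$x <- as.numeric(landmarks$x)
  landmarks$y <- as.numeric(landmarks$y)
  unknown <- setdiff(landmarks$name, landmark_names())
  if (length(unknown) > 0) {
    stop("unknown landmark name(s): ", paste(unknown, collapse = ", "))
  }
  dup <- unique(landmarks$name[duplicated(landmarks$name)])
  if (length(dup) > 0) {
    stop("duplicate landmark label(s): ", paste(dup, collapse = ", "))
  }
  if (!all(is.finite(landmarks$x)) || !all(is.finite(landmarks$y))) {
    stop("landmark coordinates must be finite")
  }
  if (!is.null(image_width) && !is.null(image_height)) {
    out <- landmarks$x < 0 | landmarks$y < 0 |
      landmarks$x > image_width | landmarks$y > image_height
    if (any(out)) {
      stop("landmark(s) outside image bounds: ",
           paste(landmarks$name[out], collapse = ", "))
    }
  }
  if (!is.null(gold_stage)) gold_stage <- as.character(as_stage(gold_stage))
  rownames(landmarks) <- NULL
  structure(
    list(image_id = as.character(image_id),
         image_width = image_width, image_height = image_height,
         landmarks = landmarks[, c("name", "x", "y")],
         gold_stage = gold_stage, rater_id = rater_id),
    class = "cvm_annotation"
  )
}

#' @export
print.cvm_annotation <- function(x, ...) {
  cat("<cvm_annotation> image:", x$image_id,
      sprintf("(%d landmarks%s)", nrow(x$landmarks),
              if (is_stageable(x)) ", stageable" else ""), "\n")
  if (!is.null(x$gold_stage)) cat("  gold stage:", x$gold_stage, "\n")
  print(x$landmarks, row.names = FALSE)
  invisible(x)
}

#' Test whether a record carries the full landmark set
#'
#' @param record a [annotation_record()].
#' @return `TRUE` if `R1`, `R2` and all 13 anatomic landmarks are present.
#' @export
is_stageable <- function(record) {
  all(landmark_names() %in% record$landmarks$name)
}

#' Look up landmark coordinates by name
#'
#' @param record a [annotation_record()].
#' @param names character vector of landmark names.
#' @return Numeric matrix with one row per requested landmark (columns `x`,
#'   `y`); errors naming the first missing landmark.
#' @export
get_points <- function(record, names) {
  idx <- match(names, record$landmarks$name)
  if (anyNA(idx)) {
    stop("missing landmark(s): ", paste(names[is.na(idx)], collapse = ", "))
  }
  m <- as.matrix(record$landmarks[idx, c("x", "y")])
  rownames(m) <- names
  m
}

#' Read a LabelMe point annotation
#'
#' Parses the LabelMe JSON dialect (top-level `shapes` list; each shape with
#' `label`, `points`, `shape_type`). Only point-type shapes with a recognized
#' landmark label are kept; unknown labels and non-point shapes are reported
#' with a warning rather than dropped silently. A gold stage and rater id
#' written by [write_labelme()] are recovered from the `flags` field.
#'
#' @param json_text a JSON string, or a path to a `.json` file.
#' @return A [annotation_record()].
#' @export
read_labelme <- function(json_text) {
  if (length(json_text) == 1 && !grepl("[{]", json_text) && file.exists(json_text)) {
    json_text <- paste(readLines(json_text, warn = FALSE), collapse = "\n")
  }
  doc <- tryCatch(jsonlite::fromJSON(json_text, simplifyVector = FALSE),
                  error = function(e) stop("malformed LabelMe JSON: ",
                                           conditionMessage(e)))
  shapes <- doc$shapes
  if (is.null(shapes)) stop("malformed LabelMe JSON: no 'shapes' field")
  keep <- list()
  for (sh in shapes) {
    type <- if (is.null(sh$shape_type)) "point" else sh$shape_type
    label <- as.character(sh$label)
    if (!identical(type, "point")) {
      warning("ignoring non-point shape of type '", type, "' (label '",
              label, "')", call. = FALSE)
      next
    }
    if (!label %in% landmark_names()) {
      warning("ignoring unknown landmark label '", label, "'", call. = FALSE)
      next
    }
    p <- sh$points[[1]]
    keep[[length(keep) + 1L]] <- data.frame(
      name = label, x = as.numeric(p[[1]]), y = as.numeric(p[[2]]),
      stringsAsFactors = FALSE)
  }
  lm <- if (length(keep) > 0) do.call(rbind, keep) else
    data.frame(name = character(), x = numeric(), y = numeric())
  dup <- unique(lm$name[duplicated(lm$name)])
  if (length(dup) > 0) {
    stop("duplicate landmark label(s) in LabelMe document: ",
         paste(dup, collapse = ", "))
  }
  flags <- doc$flags
  gold <- if (!is.null(flags$cvm_stage)) as.character(flags$cvm_stage) else NULL
  rater <- if (!is.null(flags$rater_id)) as.character(flags$rater_id) else NULL
  image_id <- if (!is.null(doc$imagePath) && nzchar(doc$imagePath))
    tools::file_path_sans_ext(basename(doc$imagePath)) else "unknown"
  annotation_record(
    lm, image_id = image_id,
    image_width = if (!is.null(doc$imageWidth)) as.numeric(doc$imageWidth) else NULL,
    image_height = if (!is.null(doc$imageHeight)) as.numeric(doc$imageHeight) else NULL,
    gold_stage = gold, rater_id = rater)
}

#' Write an annotation record as LabelMe JSON
#'
#' Inverse of [read_labelme()]: `read_labelme(write_labelme(r))` recovers
#' `r` exactly. The gold stage and rater id, when present, are stored in the
#' LabelMe `flags` object.
#'
#' @param record a [annotation_record()].
#' @param path optional file path; when given the JSON is written there.
#' @return The JSON text, invisibly when `path` is given.
#' @export
write_labelme <- function(record, path = NULL) {
  shapes <- lapply(seq_len(nrow(record$landmarks)), function(i) {
    list(label = record$landmarks$name[i],
         points = list(c(record$landmarks$x[i], record$landmarks$y[i])),
         group_id = NULL, shape_type = "point", flags = structure(list(), names = character()))
  })
  flags <- list()
  if (!is.null(record$gold_stage)) flags$cvm_stage <- record$gold_stage
  if (!is.null(record$rater_id)) flags$rater_id <- record$rater_id
  doc <- list(
    version = "5.0.1",
    flags = if (length(flags) > 0) flags else structure(list(), names = character()),
    shapes = shapes,
    imagePath = paste0(record$image_id, ".png"),
    imageHeight = record$image_height,
    imageWidth = record$image_width)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                          null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' Pixel-to-millimetre calibration from the reference marker
#'
#' The two reference points `R1` and `R2` mark a segment of known 10 mm
#' physical length on the film; the scale is `10 / |R1 - R2|` millimetres per
#' pixel. Calibration is per image, since radiographic magnification varies
#' across cephalostats.
#'
#' @param record a [annotation_record()] containing `R1` and `R2`.
#' @param reference_mm physical length of the reference segment (default 10 mm).
#' @return An object of class `cvm_scale`: the scale in mm/pixel.
#' @export
compute_scale <- function(record, reference_mm = 10) {
  pts <- tryCatch(get_points(record, c("R1", "R2")),
                  error = function(e) stop("calibration error: ",
                                           conditionMessage(e)))
  d <- sqrt(sum((pts[1, ] - pts[2, ])^2))
  if (d <= 0 || !is.finite(d)) {
    stop("degenerate calibration: R1 and R2 are coincident")
  }
  structure(reference_mm / d, class = "cvm_scale")
}

#' @export
print.cvm_scale <- function(x, ...) {
  cat(sprintf("<cvm_scale> %.6g mm/pixel\n", unclass(x)))
  invisible(x)
}

#' Region-of-interest specification
#'
#' The ROI is the bounding box of the 13 anatomic landmarks, expanded by
#' `margin_fraction` of its extent on each side, resampled to a fixed
#' `width` x `height` raster (default 100 x 200 pixels) for the detector.
#'
#' @param width,height output raster size in pixels.
#' @param margin_fraction dimensionless padding around the landmark bounding
#'   box (per axis, each side).
#' @return An object of class `cvm_roi_spec`.
#' @export
roi_spec <- function(width = 100L, height = 200L, margin_fraction = 0.1) {
  stopifnot(width >= 1, height >= 1, margin_fraction >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 margin_fraction = margin_fraction),
            class = "cvm_roi_spec")
}

#' Crop and resample the C2-C4 region of interest
#'
#' Crops the padded bounding box of the anatomic landmarks out of a grayscale
#' image, resamples it to the ROI raster size with bilinear interpolation,
#' and re-expresses the landmarks in ROI pixel coordinates. The affine
#' transform is returned so that ROI coordinates map back to full-image
#' coordinates exactly (up to floating point); see [roi_to_image()].
#'
#' @param image numeric matrix (rows = y, columns = x) with values in
#'   `[0, 1]`, or `NULL` to transform coordinates only.
#' @param record a stageable [annotation_record()].
#' @param spec a [roi_spec()].
#' @return List with elements `image` (ROI raster or `NULL`), `record`
#'   (landmarks in ROI coordinates) and `transform` (list `x0`, `y0`, `sx`,
#'   `sy` such that `roi = (full - origin) * s`).
#' @export
crop_roi <- function(image, record, spec = roi_spec()) {
  if (!is_stageable(record)) stop("record is not stageable (missing landmarks)")
  pts <- get_points(record, anatomic_landmark_names())
  if (!is.null(image)) {
    h <- nrow(image); w <- ncol(image)
    out <- pts[, "x"] < 0 | pts[, "y"] < 0 | pts[, "x"] > (w - 1) | pts[, "y"] > (h - 1)
    if (any(out)) {
      stop("landmark(s) outside image bounds: ",
           paste(rownames(pts)[out], collapse = ", "))
    }
  }
  bx <- range(pts[, "x"]); by <- range(pts[, "y"])
  padx <- spec$margin_fraction * diff(bx)
  pady <- spec$margin_fraction * diff(by)
  x0 <- bx[1] - padx; x1 <- bx[2] + padx
  y0 <- by[1] - pady; y1 <- by[2] + pady
  if (x1 <= x0 || y1 <= y0) stop("degenerate landmark bounding box")
  sx <- (spec$width - 1) / (x1 - x0)
  sy <- (spec$height - 1) / (y1 - y0)
  tf <- list(x0 = x0, y0 = y0, sx = sx, sy = sy)
  lm <- record$landmarks
  lm$x <- (lm$x - x0) * sx
  lm$y <- (lm$y - y0) * sy
  roi_rec <- annotation_record(lm, image_id = record$image_id,
                               gold_stage = record$gold_stage,
                               rater_id = record$rater_id)
  roi_rec$image_width <- spec$width
  roi_rec$image_height <- spec$height
  roi_img <- NULL
  if (!is.null(image)) {
    xs <- x0 + (seq_len(spec$width) - 1) / sx
    ys <- y0 + (seq_len(spec$height) - 1) / sy
    roi_img <- bilinear_sample(image, xs, ys)
  }
  list(image = roi_img, record = roi_rec, transform = tf)
}

#' Map ROI coordinates back to full-image coordinates
#'
#' @param xy numeric matrix of ROI coordinates (columns x, y) or a
#'   `cvm_annotation` in ROI coordinates.
#' @param transform the `transform` element returned by [crop_roi()].
#' @return Object of the same type in full-image pixel coordinates.
#' @export
roi_to_image <- function(xy, transform) {
  if (inherits(xy, "cvm_annotation")) {
    lm <- xy$landmarks
    lm$x <- lm$x / transform$sx + transform$x0
    lm$y <- lm$y / transform$sy + transform$y0
    rec <- xy
    rec$landmarks <- lm
    rec$image_width <- NULL
    rec$image_height <- NULL
    return(rec)
  }
  cbind(x = xy[, 1] / transform$sx + transform$x0,
        y = xy[, 2] / transform$sy + transform$y0)
}

# bilinear resampling of a [0,1] grayscale matrix at 0-based pixel-centre
# coordinates xs (columns) and ys (rows); clamps to the image border
bilinear_sample <- function(image, xs, ys) {
  h <- nrow(image); w <- ncol(image)
  xs <- pmin(pmax(xs, 0), w - 1)
  ys <- pmin(pmax(ys, 0), h - 1)
  x0 <- floor(xs); y0 <- floor(ys)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- xs - x0; fy <- ys - y0
  # outer products build the full grid in one shot
  g <- function(yi, xi) image[cbind(rep(yi + 1, times = length(xi)),
                                    rep(xi + 1, each = length(yi)))]
  n <- length(ys); m <- length(xs)
  v00 <- matrix(g(y0, x0), n, m)
  v01 <- matrix(g(y0, x1), n, m)
  v10 <- matrix(g(y1, x0), n, m)
  v11 <- matrix(g(y1, x1), n, m)
  FY <- matrix(fy, n, m); FX <- matrix(fx, n, m, byrow = TRUE)
  v00 * (1 - FY) * (1 - FX) + v01 * (1 - FY) * FX +
    v10 * FY * (1 - FX) + v11 * FY * FX
}

#' Read a grayscale image
#'
#' Reads a PNG as a numeric matrix in `[0, 1]` (rows = y from the top,
#' columns = x). Colour images are converted to grayscale by channel
#' averaging.
#'
#' @param path path to a PNG file.
#' @return Numeric matrix.
#' @export
read_gray_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) {
    nc <- min(dim(a)[3], 3)
    a <- apply(a[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  a
}

#' Write a grayscale image
#'
#' @param image numeric matrix with values in `[0, 1]`.
#' @param path output PNG path.
#' @export
write_gray_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
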