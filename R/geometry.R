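#' Signed perpendicular point-to-line distance
#'
#' Distance from `p` to the infinite line through `a` and `b`, in pixels.
#' In the raster convention (y increasing downward) the sign is positive when
#' `p` lies on the side of the line toward decreasing y, i.e. superiorly —
#' the direction of a true concavity of a vertebral lower border. The
#' magnitude is `|cross(b - a, p - a)| / |b - a|`.
#'
#' @param p,a,b length-2 numeric vectors `(x, y)` in pixels.
#' @return Signed distance in pixels.
#' @export
point_line_distance <- function(p, a, b) {
  ab <- b - a
  len <- sqrt(sum(ab^2))
  if (len == 0) stop("degenerate line: a and b coincide")
  cross <- ab[1] * (p[2] - a[2]) - ab[2] * (p[1] - a[1])
  # y grows downward, so a point above the (left-to-right) line has negative
  # cross product; flip so that "superior" is positive
  -cross / len
}

#' Lower-border concavity depth
#'
#' Perpendicular depth, in millimetres, of the deepest lower-border point `m`
#' superior to the chord joining the posterior (`lp`) and anterior (`la`)
#' lower-border corners. Convex or flat borders (m at or inferior to the
#' chord) yield 0: stages below CS2 have *no* concavity, never a negative
#' one.
#'
#' The superior side is determined from `superior_ref` when given — reference
#' points known to lie superior to the chord (e.g. the vertebra's own
#' upper-border landmarks) — which makes the sign convention invariant under
#' rotation of the whole annotation. Without a reference the raster
#' convention (up = decreasing y) is used.
#'
#' @param lp,la,m length-2 numeric `(x, y)` pixel coordinates.
#' @param scale a [compute_scale()] result (mm/pixel), or a plain number.
#' @param superior_ref optional matrix of points (rows = points, columns x, y)
#'   defining the superior side of the chord.
#' @return Concavity depth in mm (non-negative).
#' @export
concavity_depth <- function(lp, la, m, scale = 1, superior_ref = NULL) {
  d <- point_line_distance(m, lp, la)
  if (!is.null(superior_ref)) {
    ref <- mean(apply(superior_ref, 1, function(q) point_line_distance(q, lp, la)))
    if (is.finite(ref) && ref < 0) d <- -d
  }
  max(0, d) * as.numeric(scale)
}

#' Base-to-anterior-height ratio (BAR)
#'
#' Ratio between the base length `|lp - la|` of a vertebral body and its
#' anterior height `|ua - la|`. The ratio is dimensionless, so the pixel
#' calibration cancels. As the vertebral body elongates vertically with
#' maturation the BAR falls: trapezoid/horizontal-rectangle bodies have
#' BAR well above 1, squares near 1, vertical rectangles below 1.
#'
#' @param lp,la,ua length-2 numeric `(x, y)` pixel coordinates of the
#'   posterior lower, anterior lower and anterior upper corners.
#' @param min_height_px anterior heights below this many pixels raise an
#'   error instead of producing huge ratios.
#' @return Dimensionless ratio.
#' @export
bar_ratio <- function(lp, la, ua, min_height_px = 0.5) {
  base <- sqrt(sum((lp - la)^2))
  height <- sqrt(sum((ua - la)^2))
  if (height < min_height_px) {
    stop("degenerate vertebral shape: anterior height ", signif(height, 3),
         " px below ", min_height_px, " px")
  }
  base / height
}

#' Morphometric measurement set
#'
#' Computes the five quantities that drive CVM staging from a calibrated
#' annotation: the lower-border concavity depths of C2, C3 and C4 (mm) and
#' the base-to-anterior-height ratios of C3 and C4 (dimensionless).
#'
#' The superior side of each lower-border chord is fixed from the annotation
#' itself (the vertebra's upper-border landmarks for C3/C4; for C2, which has
#' no upper-border landmarks, the side opposite the C3 body), so all five
#' measurements are invariant under rotation and translation of the whole
#' annotation.
#'
#' @param record a stageable [annotation_record()].
#' @param scale a [compute_scale()] result; computed from the record's
#'   R1/R2 when omitted.
#' @return An object of class `cvm_measurements`: named numeric vector
#'   `c2conc`, `c3conc`, `c4conc` (mm), `c3bar`, `c4bar`.
#' @export
measure_landmarks <- function(record, scale = NULL) {
  if (is.null(scale)) scale <- compute_scale(record)
  need <- anatomic_landmark_names()
  pts <- get_points(record, need)
  p <- function(nm) pts[nm, ]
  c3_upper <- pts[c("C3up", "C3ua"), , drop = FALSE]
  c4_upper <- pts[c("C4up", "C4ua"), , drop = FALSE]
  m <- structure(
    c(c2conc = concavity_depth(p("C2lp"), p("C2la"), p("C2m"), scale,
                               superior_ref = c2_superior_ref(pts)),
      c3conc = concavity_depth(p("C3lp"), p("C3la"), p("C3m"), scale,
                               superior_ref = c3_upper),
      c4conc = concavity_depth(p("C4lp"), p("C4la"), p("C4m"), scale,
                               superior_ref = c4_upper),
      c3bar = bar_ratio(p("C3lp"), p("C3la"), p("C3ua")),
      c4bar = bar_ratio(p("C4lp"), p("C4la"), p("C4ua"))),
    class = "cvm_measurements")
  m
}

# superior-side reference for the C2 chord: the point reflected from the C3
# body centroid across the C2lp-C2la line lies superior to it
c2_superior_ref <- function(pts) {
  cen <- colMeans(pts[c("C3up", "C3ua", "C3lp", "C3la"), ])
  a <- pts["C2lp", ]; b <- pts["C2la", ]
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(NULL)
  t <- sum((cen - a) * ab) / len2
  foot <- a + t * ab
  matrix(2 * foot - cen, nrow = 1)
}

#' @export
print.cvm_measurements <- function(x, ...) {
  cat("<cvm_measurements>\n")
  cat(sprintf("  concavity (mm): C2 %.3f  C3 %.3f  C4 %.3f\n",
              x["c2conc"], x["c3conc"], x["c4conc"]))
  cat(sprintf("  BAR:            C3 %.3f  C4 %.3f\n", x["c3bar"], x["c4bar"]))
  invisible(x)
}

#' Measurement constructor from raw values
#'
#' @param c2conc,c3conc,c4conc concavity depths in mm (non-negative).
#' @param c3bar,c4bar base-to-anterior-height ratios (positive).
#' @return A `cvm_measurements` object.
#' @export
measurement_set <- function(c2conc, c3conc, c4conc, c3bar, c4bar) {
  v <- c(c2conc = c2conc, c3conc = c3conc, c4conc = c4conc,
         c3bar = c3bar, c4bar = c4bar)
  if (any(!is.finite(v))) stop("measurements must be finite")
  if (any(v[1:3] < 0)) stop("concavity depths must be non-negative")
  if (any(v[4:5] <= 0)) stop("BAR values must be positive")
  structure(v, class = "cvm_measurements")
}
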