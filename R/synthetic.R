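#' Synthetic generation parameters
#'
#' Controls the stage-conditioned generator. Defaults mirror the detector's
#' working scale: a 100 x 200 pixel frame at 0.25 mm/pixel (25 x 50 mm),
#' vertebral body width 10 mm, landmark jitter and image noise off unless
#' requested. Concavity depths and BAR values are drawn uniformly from the
#' stage-consistent region of the staging thresholds, kept at least
#' `conc_margin_mm` (0.15 mm) and `bar_margin` (0.05) away from every
#' decision boundary so that zero-jitter cases are never borderline.
#'
#' @param mm_per_pixel physical pixel size (mm).
#' @param width_px,height_px rendered frame size in pixels.
#' @param body_width_mm vertebral body base width (mm).
#' @param jitter_sigma_mm isotropic Gaussian landmark jitter SD (mm).
#' @param noise_sd additive Gaussian image noise SD (intensity units).
#' @param blur_sigma_px Gaussian blur SD (pixels).
#' @param conc_margin_mm,bar_margin sampling margins from the staging
#'   thresholds.
#' @param thresholds the [cvm_thresholds()] the sampler stays consistent
#'   with.
#' @return List of class `cvm_synth_params`.
#' @export
synth_params <- function(mm_per_pixel = 0.25, width_px = 100L,
                         height_px = 200L, body_width_mm = 10,
                         jitter_sigma_mm = 0, noise_sd = 0.03,
                         blur_sigma_px = 1, conc_margin_mm = 0.15,
                         bar_margin = 0.05, thresholds = cvm_thresholds()) {
  structure(list(mm_per_pixel = mm_per_pixel, width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 body_width_mm = body_width_mm,
                 jitter_sigma_mm = jitter_sigma_mm, noise_sd = noise_sd,
                 blur_sigma_px = blur_sigma_px,
                 conc_margin_mm = conc_margin_mm, bar_margin = bar_margin,
                 thresholds = thresholds),
            class = "cvm_synth_params")
}

# uniform draws from the stage-consistent measurement regions
sample_flat_conc <- function(p) stats::runif(1, 0, max(
  0, p$thresholds$concavity_mm - p$conc_margin_mm))
sample_concave_conc <- function(p) stats::runif(
  1, p$thresholds$concavity_mm + p$conc_margin_mm,
  p$thresholds$concavity_mm + p$conc_margin_mm + 1.2)
sample_bar <- function(shape, p) {
  th <- p$thresholds
  lo_v <- 0.7 # anatomical floor keeps bodies inside the frame
  switch(shape,
    horizontal = stats::runif(1, th$square_upper_bar + p$bar_margin,
                              th$square_upper_bar + p$bar_margin + 0.35),
    square = stats::runif(1, th$vertical_upper_bar + p$bar_margin,
                          th$square_upper_bar - p$bar_margin),
    vertical = stats::runif(1, lo_v, th$vertical_upper_bar - p$bar_margin))
}

# per-stage morphology plan: which borders are concave, which shape pair
stage_plan <- function(stage, inconsistent = FALSE) {
  k <- match(stage, stage_levels())
  concave <- switch(stage,
    CS1 = c(FALSE, FALSE, FALSE),
    CS2 = c(TRUE, FALSE, FALSE),
    CS3 = c(TRUE, TRUE, FALSE),
    c(TRUE, TRUE, TRUE))
  if (inconsistent) {
    if (stage == "CS2") concave <- c(FALSE, TRUE, FALSE)
    else if (stage == "CS3") concave <- c(TRUE, FALSE, TRUE)
    else stop("inconsistent patterns exist only for CS2 and CS3")
  }
  shapes <- switch(stage,
    CS5 = {
      combos <- list(c("square", "square"), c("square", "horizontal"),
                     c("horizontal", "square"))
      combos[[sample.int(3, 1)]]
    },
    CS6 = {
      combos <- list(c("vertical", "vertical"), c("vertical", "square"),
                     c("square", "vertical"), c("vertical", "horizontal"),
                     c("horizontal", "vertical"))
      combos[[sample.int(5, 1)]]
    },
    c("horizontal", "horizontal"))
  list(concave = concave, shapes = shapes)
}

#' Generate one stage-conditioned synthetic case
#'
#' Constructs a C2 body with a three-point lower border and C3/C4
#' quadrilaterals whose concavity depths and BARs are drawn uniformly from
#' the stage-consistent region of the thresholds, places the 13 anatomic
#' landmarks analytically at the constructed extremes, adds the R1/R2
#' calibration pair at exactly 10 mm spacing, and (optionally) renders a
#' radiograph-like grayscale frame. With zero jitter,
#' [measure_landmarks()] recovers the constructed depths and ratios to
#' within 1e-9 mm and [stage_record()] recovers the stage exactly.
#'
#' @param stage target stage label (`"CS1"`..`"CS6"`).
#' @param params a [synth_params()].
#' @param image_id identifier for the case.
#' @param render logical; rasterise the image (slower) or landmarks only.
#' @param inconsistent logical; produce an anatomically out-of-order
#'   concavity pattern (same stage under the count rule, flagged
#'   `pattern_consistent = FALSE`). Only defined for CS2/CS3.
#' @param seed optional integer seed for this one case.
#' @return An object of class `cvm_case`: `record`, `image` (or `NULL`),
#'   `true_stage`, `true_measurements`, `geometry`.
#' @export
sample_case <- function(stage, params = synth_params(), image_id = NULL,
                        render = FALSE, inconsistent = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stage <- as.character(as_stage(stage))
  if (params$thresholds$concavity_mm <= params$conc_margin_mm) {
    stop("empty stage-consistent region: concavity threshold below margin")
  }
  plan <- stage_plan(stage, inconsistent)
  conc <- vapply(plan$concave, function(cc)
    if (cc) sample_concave_conc(params) else sample_flat_conc(params),
    numeric(1))
  bars <- vapply(plan$shapes, sample_bar, numeric(1), p = params)
  geom <- build_geometry(conc, bars, params)
  if (is.null(image_id)) image_id <- sprintf("synth_%s", stage)
  rec <- annotation_record(geom$landmarks, image_id = image_id,
                           image_width = params$width_px,
                           image_height = params$height_px,
                           gold_stage = stage)
  if (params$jitter_sigma_mm > 0) {
    rec <- jitter_landmarks(rec, params$jitter_sigma_mm,
                            mm_per_pixel = params$mm_per_pixel)
  }
  img <- if (render) render_image(geom, params) else NULL
  structure(
    list(record = rec, image = img, true_stage = as_stage(stage),
         true_measurements = measurement_set(conc[1], conc[2], conc[3],
                                             bars[1], bars[2]),
         geometry = geom),
    class = "cvm_case")
}

#' @export
print.cvm_case <- function(x, ...) {
  cat("<cvm_case>", x$record$image_id, "true stage",
      as.character(x$true_stage),
      if (is.null(x$image)) "(landmarks only)" else "(rendered)", "\n")
  print(x$true_measurements)
  invisible(x)
}

# vertebral column geometry in pixel coordinates; all sizes start in mm
build_geometry <- function(conc, bars, p) {
  mpp <- p$mm_per_pixel
  w <- p$body_width_mm
  x0 <- 7; x1 <- x0 + w            # body posterior/anterior x (mm)
  w2 <- w + 1                      # C2 slightly wider
  y2b <- 14                        # C2 lower border y (mm)
  gap <- 2
  y3t <- y2b + gap
  y3b <- y3t + w / bars[1]
  y4t <- y3b + gap
  y4b <- y4t + w / bars[2]
  px <- function(x, y) c(x / mpp, y / mpp)
  lm <- list(
    R1 = px(3, 8), R2 = px(3, 18),
    C2lp = px(x0, y2b), C2m = px(x0 + w2 / 2, y2b - conc[1]),
    C2la = px(x0 + w2, y2b),
    C3up = px(x0, y3t), C3ua = px(x1, y3t),
    C3lp = px(x0, y3b), C3m = px(x0 + w / 2, y3b - conc[2]),
    C3la = px(x1, y3b),
    C4up = px(x0, y4t), C4ua = px(x1, y4t),
    C4lp = px(x0, y4b), C4m = px(x0 + w / 2, y4b - conc[3]),
    C4la = px(x1, y4b))
  landmarks <- data.frame(name = names(lm),
                          x = vapply(lm, `[`, numeric(1), 1),
                          y = vapply(lm, `[`, numeric(1), 2),
                          stringsAsFactors = FALSE)
  # closed outlines for rendering: upper corners, anterior side, lower-border
  # arc through (la, m, lp), posterior side
  body_poly <- function(up, ua, lp, m, la) {
    arc <- arc_points(la, m, lp)
    rbind(matrix(up, 1), matrix(ua, 1), matrix(la, 1), arc, matrix(lp, 1))
  }
  c2_top_l <- px(x0 + 1.5, y2b - 6.5)
  c2_top_r <- px(x0 + w2 - 1, y2b - 8)
  polys <- list(
    C2 = body_poly(c2_top_l, c2_top_r, lm$C2lp, lm$C2m, lm$C2la),
    C3 = body_poly(lm$C3up, lm$C3ua, lm$C3lp, lm$C3m, lm$C3la),
    C4 = body_poly(lm$C4up, lm$C4ua, lm$C4lp, lm$C4m, lm$C4la))
  list(landmarks = landmarks, polys = polys,
       markers = list(R1 = lm$R1, R2 = lm$R2),
       width_px = p$width_px, height_px = p$height_px)
}

# points along the circular arc through a, m, b (a, b chord ends, m apex);
# degenerate (collinear) borders fall back to the straight chord
arc_points <- function(a, m, b, n = 40) {
  d <- abs((b[1] - a[1]) * (m[2] - a[2]) - (b[2] - a[2]) * (m[1] - a[1]))
  if (d < 1e-9) {
    t <- seq(0, 1, length.out = n)
    return(cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2])))
  }
  cen <- circumcenter(a, m, b)
  r <- sqrt(sum((a - cen)^2))
  th_a <- atan2(a[2] - cen[2], a[1] - cen[1])
  th_m <- atan2(m[2] - cen[2], m[1] - cen[1])
  th_b <- atan2(b[2] - cen[2], b[1] - cen[1])
  # sweep from a to b in the direction that passes through m
  sweep_ccw <- (th_b - th_a) %% (2 * pi)
  pos_m_ccw <- (th_m - th_a) %% (2 * pi)
  if (pos_m_ccw <= sweep_ccw) {
    th <- th_a + seq(0, sweep_ccw, length.out = n)
  } else {
    sweep_cw <- (th_a - th_b) %% (2 * pi)
    th <- th_a - seq(0, sweep_cw, length.out = n)
  }
  cbind(cen[1] + r * cos(th), cen[2] + r * sin(th))
}

circumcenter <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
           sum(c^2) * (a[2] - b[2])) / d
  uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
           sum(c^2) * (b[1] - a[1])) / d
  c(ux, uy)
}

#' Add Gaussian landmark jitter
#'
#' Displaces each of the 13 anatomic landmarks independently by an isotropic
#' Gaussian (SD `sigma_mm`, converted to pixels through the record's
#' calibration). The reference points R1/R2 are never moved, so the
#' calibration scale is unchanged. The per-landmark displacement magnitude
#' is then Rayleigh(`sigma_mm`)-distributed with mean
#' `sigma_mm * sqrt(pi / 2)`.
#'
#' @param record a [annotation_record()].
#' @param sigma_mm jitter SD in mm (non-negative).
#' @param mm_per_pixel calibration; derived from R1/R2 when omitted.
#' @return The jittered record.
#' @export
jitter_landmarks <- function(record, sigma_mm, mm_per_pixel = NULL) {
  if (sigma_mm < 0) stop("sigma_mm must be non-negative")
  if (sigma_mm == 0) return(record)
  if (is.null(mm_per_pixel)) mm_per_pixel <- as.numeric(compute_scale(record))
  sigma_px <- sigma_mm / mm_per_pixel
  idx <- which(record$landmarks$name %in% anatomic_landmark_names())
  n <- length(idx)
  record$landmarks$x[idx] <- record$landmarks$x[idx] + stats::rnorm(n, 0, sigma_px)
  record$landmarks$y[idx] <- record$landmarks$y[idx] + stats::rnorm(n, 0, sigma_px)
  record
}

#' Render a synthetic case as a grayscale frame
#'
#' Rasterises the vertebral-body outlines (lower borders drawn as the
#' circular arc through lp, m, la) as filled polygons over a darker
#' background, stamps small bright disks at the R1/R2 markers, then applies
#' Gaussian blur and additive Gaussian noise. With blur and noise off, the
#' polygon interiors are exactly the foreground constant.
#'
#' @param geom a `cvm_case` or its `geometry` element.
#' @param params a [synth_params()] (noise/blur settings).
#' @param foreground,background intensity constants in `[0, 1]`.
#' @return Numeric matrix `height_px` x `width_px` in `[0, 1]`.
#' @export
render_image <- function(geom, params = synth_params(), foreground = 0.8,
                         background = 0.2) {
  if (inherits(geom, "cvm_case")) geom <- geom$geometry
  h <- geom$height_px; w <- geom$width_px
  img <- matrix(background, h, w)
  mask <- matrix(FALSE, h, w)
  for (poly in geom$polys) mask <- mask | polygon_mask(poly, w, h)
  img[mask] <- foreground
  for (mk in geom$markers) {
    xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
    ys <- matrix(0:(h - 1), h, w)
    img[(xs - mk[1])^2 + (ys - mk[2])^2 <= 4] <- 1.0
  }
  if (params$blur_sigma_px > 0) img <- gaussian_blur(img, params$blur_sigma_px)
  if (params$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, params$noise_sd)
  }
  pmin(pmax(img, 0), 1)
}

# even-odd rule polygon fill over 0-based pixel centres
polygon_mask <- function(poly, w, h) {
  px <- rep(0:(w - 1), each = h)
  py <- rep(0:(h - 1), times = w)
  inside <- rep(FALSE, w * h)
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  j <- n
  for (i in seq_len(n)) {
    yi <- ys[i]; yj <- ys[j]; xi <- xs[i]; xj <- xs[j]
    if (yi != yj) {
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  matrix(inside, h, w)
}

# separable Gaussian blur with replicate-edge padding
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur1d <- function(m) { # along rows (dim 1)
    n <- nrow(m)
    idx <- outer(seq_len(n), -r:r, `+`)
    idx <- pmin(pmax(idx, 1L), n)
    out <- matrix(0, n, ncol(m))
    for (s in seq_along(k)) out <- out + k[s] * m[idx[, s], , drop = FALSE]
    out
  }
  t(blur1d(t(blur1d(img))))
}

#' Dataset composition of the emulated study
#'
#' Per-stage image counts of the training split the generator emulates by
#' default (CS1..CS6), totalling 980 cases.
#'
#' @return Named integer vector of length 6.
#' @export
default_stage_counts <- function() {
  stats::setNames(c(242L, 214L, 164L, 108L, 52L, 200L), stage_levels())
}

#' Generate a synthetic dataset on disk
#'
#' Draws `counts[s]` cases per stage, deterministic in `seed`, and (when
#' `dir` is given) writes for each case a PNG frame, a LabelMe JSON
#' annotation carrying the gold stage, and a `manifest.csv` with columns
#' `image_id`, `true_stage`.
#'
#' @param counts per-stage case counts (length 6, CS1..CS6); defaults to
#'   [default_stage_counts()].
#' @param params a [synth_params()].
#' @param seed integer seed.
#' @param dir output directory (created); `NULL` keeps everything in memory.
#' @param render logical; rasterise images (required when writing PNGs).
#' @return Invisibly, list with `cases` and `manifest` (data frame).
#' @export
generate_dataset <- function(counts = default_stage_counts(),
                             params = synth_params(), seed = 1, dir = NULL,
                             render = !is.null(dir)) {
  stopifnot(length(counts) == 6, all(counts >= 0))
  set.seed(seed)
  if (!is.null(dir) && !dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  cases <- list()
  rows <- list()
  for (si in 1:6) {
    stage <- stage_levels()[si]
    for (j in seq_len(counts[si])) {
      id <- sprintf("%s_%03d", stage, j)
      cs <- sample_case(stage, params, image_id = id, render = render)
      cases[[id]] <- cs
      rows[[id]] <- data.frame(image_id = id, true_stage = stage,
                               stringsAsFactors = FALSE)
      if (!is.null(dir)) {
        if (render) write_gray_image(cs$image, file.path(dir, paste0(id, ".png")))
        write_labelme(cs$record, file.path(dir, paste0(id, ".json")))
      }
    }
  }
  manifest <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(image_id = character(), true_stage = character())
  rownames(manifest) <- NULL
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  invisible(list(cases = cases, manifest = manifest))
}
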