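# shared fixture builders; everything is constructed in code

# a hand-placed stageable record: flat lower borders, square-ish bodies,
# R1-R2 spaced 50 px apart (0.2 mm/px)
flat_record <- function(c3bar = 1.0, c4bar = 1.0, image_id = "fix") {
  w <- 40 # body base width, px
  h3 <- w / c3bar
  h4 <- w / c4bar
  x0 <- 60; x1 <- x0 + w
  pts <- list(
    R1 = c(10, 10), R2 = c(10, 60),
    C2lp = c(x0, 100), C2m = c(x0 + w / 2, 100), C2la = c(x1, 100),
    C3up = c(x0, 110), C3ua = c(x1, 110),
    C3lp = c(x0, 110 + h3), C3m = c(x0 + w / 2, 110 + h3),
    C3la = c(x1, 110 + h3),
    C4up = c(x0, 120 + h3), C4ua = c(x1, 120 + h3),
    C4lp = c(x0, 120 + h3 + h4), C4m = c(x0 + w / 2, 120 + h3 + h4),
    C4la = c(x1, 120 + h3 + h4))
  annotation_record(pts, image_id = image_id)
}

# move a named landmark by (dx, dy) pixels
nudge <- function(record, name, dx = 0, dy = 0) {
  i <- match(name, record$landmarks$name)
  record$landmarks$x[i] <- record$landmarks$x[i] + dx
  record$landmarks$y[i] <- record$landmarks$y[i] + dy
  record
}

# rotate + translate all landmarks (rigid motion) about the origin
rigid_motion <- function(record, theta = 0, dx = 0, dy = 0) {
  x <- record$landmarks$x; y <- record$landmarks$y
  record$landmarks$x <- cos(theta) * x - sin(theta) * y + dx
  record$landmarks$y <- sin(theta) * x + cos(theta) * y + dy
  record
}

# minimal LabelMe JSON text from label -> point pairs
labelme_json <- function(points, extra_shapes = "") {
  shapes <- vapply(names(points), function(nm) {
    sprintf('{"label": "%s", "points": [[%g, %g]], "shape_type": "point"}',
            nm, points[[nm]][1], points[[nm]][2])
  }, character(1))
  all_shapes <- paste(c(shapes, if (nzchar(extra_shapes)) extra_shapes),
                      collapse = ", ")
  sprintf('{"version": "5.0.1", "shapes": [%s], "imagePath": "img.png"}',
          all_shapes)
}

# published per-stage evaluation summaries of the reference study
# (test-set composition and per-stage precision/recall/specificity/F1)
reference_staging_summary <- function() {
  list(n = c(13, 11, 5, 24, 12, 35),
       precision = c(0.67, 1.00, 0.25, 0.83, 0.46, 1.00),
       recall = c(0.92, 0.36, 0.40, 0.63, 1.00, 0.74),
       specificity = c(0.93, 1.00, 0.94, 0.96, 0.84, 1.00),
       f1 = c(0.77, 0.53, 0.31, 0.71, 0.63, 0.85),
       accuracy = 0.71)
}

# published per-landmark mean labelling errors (mm): human-human and
# AI-human columns of the reference study's landmark table
reference_landmark_means <- function() {
  list(
    human_human = c(0.38, 0.70, 0.41, 0.56, 0.54, 0.41, 0.57, 0.32, 0.50,
                    0.53, 0.37, 0.62, 0.35),
    ai_human = c(0.29, 0.47, 0.35, 0.48, 0.42, 0.24, 0.37, 0.24, 0.42,
                 0.43, 0.25, 0.46, 0.27))
}
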