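test_that("zero-jitter cases are staged back perfectly for every stage", {
  set.seed(8)
  for (s in stage_levels()) {
    for (i in 1:25) {
      cs <- sample_case(s)
      st <- stage_record(cs$record)
      expect_equal(as.character(st$stage), s)
      expect_true(st$pattern_consistent)
      expect_lt(max(abs(as.numeric(measure_landmarks(cs$record)) -
                          as.numeric(cs$true_measurements))), 1e-9)
    }
  }
})

test_that("sampled measurements keep a safety margin from every boundary", {
  set.seed(13)
  thr <- cvm_thresholds()
  for (s in stage_levels()) for (i in 1:20) {
    m <- sample_case(s)$true_measurements
    conc <- as.numeric(m)[1:3]
    bars <- as.numeric(m)[4:5]
    expect_true(all(abs(conc - thr$concavity_mm) >= 0.15 - 1e-12))
    expect_true(all(abs(bars - thr$square_upper_bar) >= 0.05 - 1e-12))
    expect_true(all(abs(bars - thr$vertical_upper_bar) >= 0.05 - 1e-12))
  }
})

test_that("CS6 cases always contain a vertical body; generation is seeded", {
  thr <- cvm_thresholds()
  for (i in 1:10) {
    cs <- sample_case("CS6", seed = 100 + i)
    bars <- as.numeric(cs$true_measurements)[4:5]
    expect_true(any(bars <= thr$vertical_upper_bar))
  }
  a <- sample_case("CS3", render = TRUE, seed = 7)
  b <- sample_case("CS3", render = TRUE, seed = 7)
  expect_identical(a$record$landmarks, b$record$landmarks)
  expect_identical(a$image, b$image)
})

test_that("inconsistent patterns keep the count-rule stage but are flagged", {
  set.seed(19)
  cs <- sample_case("CS2", inconsistent = TRUE)
  st <- stage_record(cs$record)
  expect_equal(as.character(st$stage), "CS2")
  expect_false(st$pattern_consistent)
  expect_true(st$concave_c3 && !st$concave_c2)
  expect_error(sample_case("CS1", inconsistent = TRUE), "inconsistent")
})

test_that("jitter: identity at sigma 0, R1/R2 fixed, Rayleigh mean at 0.4 mm", {
  set.seed(29)
  cs <- sample_case("CS4")
  expect_identical(jitter_landmarks(cs$record, 0), cs$record)
  j <- jitter_landmarks(cs$record, 0.7)
  expect_identical(get_points(j, c("R1", "R2")),
                   get_points(cs$record, c("R1", "R2")))
  expect_equal(as.numeric(compute_scale(j)), as.numeric(compute_scale(cs$record)))
  expect_error(jitter_landmarks(cs$record, -1), "non-negative")

  # displacement magnitudes are Rayleigh(sigma): mean sigma * sqrt(pi/2)
  sigma <- 0.4
  nms <- anatomic_landmark_names()
  base <- get_points(cs$record, nms)
  d <- replicate(500, {
    jj <- jitter_landmarks(cs$record, sigma)
    sqrt(rowSums((get_points(jj, nms) - base)^2)) * 0.25
  })
  mc_tol <- 4 * sigma * sqrt(2 - pi / 2) / sqrt(length(d))
  expect_equal(mean(d), sigma * sqrt(pi / 2), tolerance = mc_tol / (sigma * sqrt(pi / 2)))
})

test_that("rendering: exact foreground plateau, arc apex alignment, noise field", {
  p0 <- synth_params(noise_sd = 0, blur_sigma_px = 0)
  set.seed(37)
  cs <- sample_case("CS3", params = p0, render = TRUE)
  vals <- sort(unique(as.vector(cs$image)))
  expect_true(all(vals %in% c(0.2, 0.8, 1.0))) # bg, bodies, markers
  # C3m is the deepest point of the lower-border concavity: in its pixel
  # column the bottommost C3-body pixel sits at the arc apex, i.e. at C3m
  m <- get_points(cs$record, "C3m")
  up <- get_points(cs$record, "C3up")
  c4up <- get_points(cs$record, "C4up")
  col <- round(m[1, "x"]) + 1
  body_rows <- which(cs$image[, col] == 0.8)
  body_rows <- body_rows[body_rows > up[1, "y"] & body_rows < c4up[1, "y"]]
  expect_lt(abs(max(body_rows) - 1 - m[1, "y"]), 1.6)

  # same geometry, different noise fields
  pn <- synth_params(noise_sd = 0.05, blur_sigma_px = 0)
  set.seed(1); img1 <- render_image(cs, pn)
  set.seed(2); img2 <- render_image(cs, pn)
  set.seed(1); img1b <- render_image(cs, pn)
  expect_identical(img1, img1b)
  expect_false(identical(img1, img2))
  expect_lt(sd((img1 - img2)[cs$image == 0.8]), 0.05 * sqrt(2) * 1.2)
})

test_that("dataset generation writes a deterministic on-disk corpus", {
  dir1 <- file.path(tempdir(), "synth_a")
  dir2 <- file.path(tempdir(), "synth_b")
  unlink(c(dir1, dir2), recursive = TRUE)
  out1 <- generate_dataset(rep(2L, 6), seed = 7, dir = dir1)
  out2 <- generate_dataset(rep(2L, 6), seed = 7, dir = dir2)
  expect_equal(nrow(out1$manifest), 12)
  expect_equal(table(out1$manifest$true_stage)[stage_levels()],
               table(factor(rep(stage_levels(), each = 2),
                            levels = stage_levels())),
               ignore_attr = TRUE)
  expect_identical(readLines(file.path(dir1, "manifest.csv")),
                   readLines(file.path(dir2, "manifest.csv")))
  f <- file.path(dir1, "CS4_001.json")
  expect_true(file.exists(f))
  expect_identical(readLines(f), readLines(file.path(dir2, "CS4_001.json")))
  rec <- read_labelme(f)
  expect_true(is_stageable(rec))
  expect_equal(rec$gold_stage, "CS4")
  img <- read_gray_image(file.path(dir1, "CS1_001.png"))
  expect_equal(dim(img), c(200, 100))
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("default composition mirrors the emulated training split", {
  counts <- default_stage_counts()
  expect_equal(sum(counts), 980)
  expect_equal(unname(round(100 * counts / sum(counts))),
               c(25, 22, 17, 11, 5, 20))
})
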