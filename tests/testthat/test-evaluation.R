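test_that("confusion matrix counts gold/pred pairs", {
  cm <- confusion_matrix(rep("CS1", 5), rep("CS1", 5))
  expect_equal(diag(unclass(cm)), setNames(c(5, 0, 0, 0, 0, 0), stage_levels()))
  cm2 <- confusion_matrix(c("CS1", "CS2"), c("CS2", "CS2"))
  expect_equal(unclass(cm2)["CS1", "CS2"], 1)
  expect_equal(unclass(cm2)["CS2", "CS2"], 1)
  expect_error(confusion_matrix(character(), character()), "empty")
  expect_error(confusion_matrix("CS1", c("CS1", "CS2")), "length")
})

test_that("per-class one-vs-rest metrics match hand-computed counts", {
  # a class with TP = 12, FP = 6, FN = 1, TN = 81
  cm <- matrix(0, 6, 6)
  cm[1, 1] <- 12; cm[1, 2] <- 1; cm[2, 1] <- 6; cm[2, 2] <- 81
  pc <- per_class_metrics(as_confusion(cm), "CS1")
  expect_equal(pc$tp, 12); expect_equal(pc$fp, 6)
  expect_equal(pc$fn, 1); expect_equal(pc$tn, 81)
  expect_equal(pc$precision, 12 / 18, tolerance = 1e-12)
  expect_equal(pc$recall, 12 / 13, tolerance = 1e-12)
  expect_equal(pc$specificity, 81 / 87, tolerance = 1e-12)
  expect_equal(round_half_up(pc$f1, 2), 0.77)
})

test_that("perfect classifier scores 1 everywhere; absent class is undefined", {
  cm <- as_confusion(diag(c(5, 4, 3, 2, 1, 6)))
  pc <- per_class_metrics(cm)
  expect_true(all(pc$precision == 1 & pc$recall == 1 &
                    pc$specificity == 1 & pc$f1 == 1))
  expect_equal(overall_accuracy(cm), 1)
  # CS6 absent from gold and pred: recall undefined, specificity 1
  cm2 <- as_confusion(diag(c(5, 4, 3, 2, 1, 0)))
  pc6 <- per_class_metrics(cm2, "CS6")
  expect_true(is.na(pc6$recall))
  expect_true(is.na(pc6$precision))
  expect_equal(pc6$specificity, 1)
})

test_that("F1 is the harmonic mean with an undefined marker at (0, 0)", {
  expect_equal(round_half_up(f1_from_pr(1.00, 0.74), 2), 0.85)
  expect_equal(round_half_up(f1_from_pr(0.25, 0.40), 2), 0.31)
  for (x in c(0.1, 0.5, 0.77, 1)) expect_equal(f1_from_pr(x, x), x)
  expect_true(is.na(f1_from_pr(0, 0)))
})

test_that("accuracy is trace over total", {
  expect_equal(overall_accuracy(as_confusion(diag(1:6))), 1)
  off <- matrix(1, 6, 6); diag(off) <- 0
  expect_equal(overall_accuracy(as_confusion(off)), 0)
  expect_error(overall_accuracy(as_confusion(matrix(0, 6, 6))), "empty")
})

test_that("Cohen's kappa: perfect, hand-computed and chance-level cases", {
  expect_equal(cohen_kappa(as_confusion(diag(1:6))), 1)
  expect_equal(cohen_kappa(matrix(c(25, 10, 5, 60), 2)),
               (0.85 - 0.56) / 0.44, tolerance = 1e-12)
  # rank-1 expected table: independent raters agree only by chance
  p <- c(0.5, 0.3, 0.2)
  ind <- outer(p, p) * 1000
  expect_equal(cohen_kappa(ind), 0, tolerance = 1e-12)
  expect_true(is.na(cohen_kappa(matrix(c(9, 0, 0, 0), 2))))
})

test_that("kappa never exceeds accuracy and equals 1 iff diagonal", {
  set.seed(31)
  for (i in 1:50) {
    cm <- matrix(rpois(36, 3), 6, 6)
    if (sum(cm) == 0) next
    acc <- overall_accuracy(as_confusion(cm))
    k <- cohen_kappa(cm)
    if (!is.na(k)) expect_lte(k, acc + 1e-12)
    if (sum(cm) - sum(diag(cm)) > 0) expect_lt(k, 1)
  }
})

test_that("accuracy equals the count-weighted mean of per-class recall", {
  set.seed(37)
  for (i in 1:25) {
    cm <- as_confusion(matrix(rpois(36, 4), 6, 6))
    pc <- per_class_metrics(cm)
    n_g <- pc$tp + pc$fn
    expect_equal(sum(pc$recall * n_g, na.rm = TRUE) / sum(cm),
                 overall_accuracy(cm), tolerance = 1e-12)
    expect_equal(sum(pc$tp), sum(diag(unclass(cm))))
    expect_equal(sum(pc$fp), sum(cm) - sum(diag(unclass(cm))))
  }
})

test_that("metrics are equivariant under class relabelling", {
  set.seed(53)
  cm <- matrix(rpois(36, 4), 6, 6)
  perm <- sample(6)
  pc <- per_class_metrics(as_confusion(cm))
  pcp <- per_class_metrics(as_confusion(cm[perm, perm]))
  expect_equal(pcp$f1, pc$f1[perm])
  expect_equal(cohen_kappa(cm[perm, perm]), cohen_kappa(cm))
})

test_that("ICC: analytic limits, variant ordering and independence", {
  spread <- cbind(1:10, 1:10)
  expect_equal(icc(spread), 1)
  shifted <- cbind(1:10, 1:10 + 5)
  expect_lt(icc(shifted, "ICC2"), icc(shifted, "ICC3"))
  expect_equal(icc(shifted, "ICC3"), 1)
  set.seed(61)
  r <- cbind(rnorm(100), rnorm(100))
  expect_lt(abs(icc(r)), 0.15)
  expect_true(is.na(icc(matrix(3, 5, 2))))
  expect_error(icc(matrix(1, 1, 2)), "at least 2")
})

test_that("ICC(2,1) from aov matches an independent mean-squares route", {
  # oracle: mean squares summed directly from the two-way layout
  icc21_oracle <- function(x) {
    n <- nrow(x); k <- ncol(x)
    gm <- mean(x)
    msr <- k * sum((rowMeans(x) - gm)^2) / (n - 1)
    msc <- n * sum((colMeans(x) - gm)^2) / (k - 1)
    sse <- sum((x - outer(rowMeans(x), rep(1, k)) -
                  outer(rep(1, n), colMeans(x)) + gm)^2)
    mse <- sse / ((n - 1) * (k - 1))
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
  set.seed(67)
  for (i in 1:20) {
    x <- matrix(rnorm(60, sd = 2), 20, 3) + rnorm(20)
    expect_equal(icc(x, "ICC2"), icc21_oracle(x), tolerance = 1e-9)
  }
})

test_that("landmark errors: zero case, 3-4-5 offset and pairing checks", {
  set.seed(73)
  truth <- lapply(1:3, function(i) {
    # translate each image rigidly so calibration stays exactly 0.2 mm/px
    rigid_motion(flat_record(image_id = paste0("img", i)),
                 dx = runif(1, -5, 5), dy = runif(1, -5, 5))
  })
  rep0 <- landmark_errors(truth, truth)
  expect_equal(rep0$total_mean, 0)
  expect_true(all(rep0$per_landmark$mean_mm == 0))

  pred <- truth
  i <- match("C3m", pred[[1]]$landmarks$name)
  pred[[1]]$landmarks$x[i] <- pred[[1]]$landmarks$x[i] + 3
  pred[[1]]$landmarks$y[i] <- pred[[1]]$landmarks$y[i] + 4
  rep1 <- landmark_errors(pred, truth) # flat_record scale is 0.2 mm/px
  expect_equal(rep1$distances["img1", "C3m"], 5 * 0.2)
  bad <- truth
  bad[[1]]$image_id <- "other"
  expect_error(landmark_errors(bad, truth), "pairing")
})

test_that("total-row convention reproduces the published summary rows", {
  ref <- reference_landmark_means()
  hh <- summarize_landmark_means(ref$human_human)
  ai <- summarize_landmark_means(ref$ai_human)
  expect_equal(round_half_up(hh$total_mean, 2), 0.48)
  expect_equal(round_half_up(hh$total_sd, 2), 0.12)
  expect_equal(round_half_up(ai$total_mean, 2), 0.36)
  expect_equal(round_half_up(ai$total_sd, 2), 0.09)
})

test_that("report rounding is half-up at 2 decimals", {
  # 0.125 is exactly representable; base round() would give 0.12 (half-even)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(2.5, 0), 3)
})
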