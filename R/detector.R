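#' Detector configuration
#'
#' Configuration of the convolutional landmark regressor: an ROI-sized
#' grayscale frame goes in, the 30-vector of 15 normalized landmark
#' coordinates comes out of a single fully connected layer, and training
#' minimises mean squared error with Adam. The optimiser settings follow the
#' reference pipeline (batch 32, learning rate 1e-4, epsilon 1e-8); the
#' backbone is a compact stack of 3x3 convolutions (depth and channel widths
#' configurable) rather than a large dilated residual network, and the desk
#' default is 30 epochs.
#'
#' @param input_width,input_height frame size in pixels.
#' @param conv_channels integer vector of output channels per conv layer.
#' @param conv_strides stride per conv layer (same length).
#' @param epochs,batch_size training schedule.
#' @param learning_rate,epsilon Adam settings.
#' @param seed integer seed controlling initialization and data order.
#' @return List of class `cvm_detector_config`.
#' @export
detector_config <- function(input_width = 100L, input_height = 200L,
                            conv_channels = c(8L, 16L, 32L, 32L, 32L, 32L),
                            conv_strides = c(2L, 2L, 2L, 2L, 1L, 1L),
                            epochs = 30L, batch_size = 32L,
                            learning_rate = 1e-4, epsilon = 1e-8,
                            seed = 1L) {
  stopifnot(length(conv_channels) == length(conv_strides),
            all(conv_channels >= 1), all(conv_strides >= 1),
            epochs >= 1, batch_size >= 1, learning_rate >= 0)
  structure(list(input_width = as.integer(input_width),
                 input_height = as.integer(input_height),
                 conv_channels = as.integer(conv_channels),
                 conv_strides = as.integer(conv_strides),
                 n_outputs = 2L * length(landmark_names()),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "cvm_detector_config")
}

conv_out_dim <- function(d, stride, k = 3L, pad = 1L) {
  out <- (d + 2L * pad - k) %/% stride + 1L
  if (out < 1) stop("shape error: feature map collapses below 1 pixel; ",
                    "reduce conv depth/strides for this input size")
  out
}

#' Build an (untrained) landmark detector
#'
#' Initialises the conv stack (He-scaled Gaussian weights) and the fully
#' connected output layer, deterministically in `config$seed`.
#'
#' @param config a [detector_config()].
#' @return Object of class `cvm_detector` with `trained = FALSE`.
#' @export
build_detector <- function(config = detector_config()) {
  set.seed(config$seed)
  k <- 3L
  h <- config$input_height; w <- config$input_width; cin <- 1L
  layers <- list()
  for (i in seq_along(config$conv_channels)) {
    cout <- config$conv_channels[i]
    fan_in <- k * k * cin
    layers[[i]] <- list(
      W = matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout),
      b = numeric(cout), stride = config$conv_strides[i],
      in_h = h, in_w = w, in_c = cin)
    h <- conv_out_dim(h, config$conv_strides[i])
    w <- conv_out_dim(w, config$conv_strides[i])
    cin <- cout
  }
  flat <- h * w * cin
  if (flat < config$n_outputs) {
    stop("shape error: flattened feature dimension (", flat,
         ") is smaller than the ", config$n_outputs,
         "-coordinate output; the input is too small for this conv stack")
  }
  fc <- list(W = matrix(stats::rnorm(flat * config$n_outputs, 0,
                                     sqrt(1 / flat)), flat, config$n_outputs),
             b = numeric(config$n_outputs))
  structure(list(config = config, conv = layers, fc = fc,
                 out_h = h, out_w = w, out_c = cin,
                 trained = FALSE, loss_history = numeric(0)),
            class = "cvm_detector")
}

# ---- im2col convolution machinery ------------------------------------------
# feature maps are arrays (H, W, C, N); indices are built once per layer
# shape and reused across the batch

conv_indices <- function(H, W, C, k = 3L, stride = 1L, pad = 1L) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  oy <- (seq_len(Ho) - 1L) * stride # top-left of each window (0-based)
  ox <- (seq_len(Wo) - 1L) * stride
  base <- outer(oy, ox * Hp, `+`) # (Ho, Wo) linear offsets within a channel
  base <- as.vector(base) # P = Ho*Wo, column-major (ho fastest)
  off <- as.vector(outer(seq_len(k) - 1L,
                         (seq_len(k) - 1L) * Hp, `+`)) # within-window
  off <- as.vector(outer(off, (seq_len(C) - 1L) * (Hp * Wp), `+`)) # + channel
  idx <- outer(base, off, `+`) + 1L # (P, k*k*C), into one padded image
  list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp, P = Ho * Wo)
}

pad_maps <- function(x, pad = 1L) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

# batch gather index: per-image window indices offset by image stride
batch_indices <- function(ci, N, per_img) {
  idxN <- ci$idx[rep(seq_len(ci$P), times = N), , drop = FALSE]
  idxN + rep((seq_len(N) - 1L) * per_img, each = ci$P)
}

conv_forward <- function(x, layer, ci, idx_cache = NULL, key = NULL) {
  d <- dim(x); N <- d[4]
  xp <- pad_maps(x)
  per_img <- prod(dim(xp)[1:3])
  idxN <- if (!is.null(idx_cache) && !is.null(idx_cache[[key]]))
    idx_cache[[key]] else batch_indices(ci, N, per_img)
  if (!is.null(idx_cache)) idx_cache[[key]] <- idxN
  col <- xp[idxN]
  dim(col) <- dim(idxN)
  z <- col %*% layer$W
  z <- sweep(z, 2, layer$b, `+`)
  a <- array(z, c(ci$Ho, ci$Wo, N, ncol(z)))
  a <- aperm(a, c(1, 2, 4, 3)) # (Ho, Wo, Cout, N)
  list(out = pmax(a, 0), pre = a, col = col, idxN = idxN,
       in_dim = d, pad_dim = dim(xp))
}

conv_backward <- function(dout, layer, cache, ci) {
  relu_mask <- cache$pre > 0
  dout <- dout * relu_mask
  N <- dim(dout)[4]
  D <- aperm(dout, c(1, 2, 4, 3))
  dim(D) <- c(ci$P * N, dim(dout)[3])
  dW <- crossprod(cache$col, D)
  db <- colSums(D)
  dcol <- tcrossprod(D, layer$W)
  dxp <- numeric(prod(cache$pad_dim))
  for (kk in seq_len(ncol(dcol))) {
    ids <- cache$idxN[, kk]
    dxp[ids] <- dxp[ids] + dcol[, kk]
  }
  dxp <- array(dxp, cache$pad_dim)
  d <- cache$in_dim
  dx <- dxp[1L + seq_len(d[1]), 1L + seq_len(d[2]), , , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

detector_forward <- function(det, x, want_cache = FALSE,
                             idx_cache = NULL, cis = NULL) {
  # x: array (H, W, 1, N), intensities in [0, 1]
  caches <- vector("list", length(det$conv))
  if (is.null(cis)) cis <- detector_conv_indices(det)
  N <- dim(x)[4]
  for (i in seq_along(det$conv)) {
    cc <- conv_forward(x, det$conv[[i]], cis[[i]], idx_cache = idx_cache,
                       key = paste0("L", i, "_N", N))
    caches[[i]] <- cc
    x <- cc$out
  }
  N <- dim(x)[4]
  flat <- matrix(x, prod(dim(x)[1:3]), N) # (F, N), column-major per image
  pred <- t(flat) %*% det$fc$W
  pred <- sweep(pred, 2, det$fc$b, `+`) # (N, 30)
  if (!want_cache) return(pred)
  list(pred = pred, caches = caches, flat = flat, cis = cis,
       conv_out_dim = dim(x))
}

detector_conv_indices <- function(det) {
  lapply(det$conv, function(ly)
    conv_indices(ly$in_h, ly$in_w, ly$in_c, stride = ly$stride))
}

detector_backward <- function(det, fw, target) {
  N <- nrow(fw$pred)
  dpred <- 2 * (fw$pred - target) / length(target) # d mean((p - t)^2)
  dfcW <- fw$flat %*% dpred
  dfcb <- colSums(dpred)
  dflat <- det$fc$W %*% t(dpred) # (F, N)
  dx <- array(dflat, fw$conv_out_dim)
  grads <- vector("list", length(det$conv))
  for (i in rev(seq_along(det$conv))) {
    g <- conv_backward(dx, det$conv[[i]], fw$caches[[i]], fw$cis[[i]])
    grads[[i]] <- g[c("dW", "db")]
    dx <- g$dx
  }
  list(conv = grads, fc = list(dW = dfcW, db = dfcb))
}

adam_init <- function(det) {
  zero_like <- function(p) lapply(p, function(v) v * 0)
  list(m = list(conv = lapply(det$conv, function(l) zero_like(l[c("W", "b")])),
                fc = zero_like(det$fc[c("W", "b")])),
       v = list(conv = lapply(det$conv, function(l) zero_like(l[c("W", "b")])),
                fc = zero_like(det$fc[c("W", "b")])),
       t = 0L)
}

adam_update <- function(det, grads, state, lr, eps, b1 = 0.9, b2 = 0.999) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  step <- function(p, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  for (i in seq_along(det$conv)) {
    for (nm in c("W", "b")) {
      gnm <- paste0("d", nm)
      u <- step(det$conv[[i]][[nm]], grads$conv[[i]][[gnm]],
                state$m$conv[[i]][[nm]], state$v$conv[[i]][[nm]])
      det$conv[[i]][[nm]] <- u$p
      state$m$conv[[i]][[nm]] <- u$m
      state$v$conv[[i]][[nm]] <- u$v
    }
  }
  for (nm in c("W", "b")) {
    gnm <- paste0("d", nm)
    u <- step(det$fc[[nm]], grads$fc[[gnm]], state$m$fc[[nm]], state$v$fc[[nm]])
    det$fc[[nm]] <- u$p
    state$m$fc[[nm]] <- u$m
    state$v$fc[[nm]] <- u$v
  }
  list(det = det, state = state)
}

#' Assemble a training dataset from synthetic cases
#'
#' Stacks rendered frames and converts each case's 15 landmarks to the
#' normalized 30-vector the detector regresses: coordinates divided by
#' `(width - 1)` and `(height - 1)`, ordered as
#' `(x, y)` pairs in the fixed [landmark_names()] order (part of the
#' serialization contract).
#'
#' @param cases list of `cvm_case` objects with rendered images.
#' @return List with `images` (array H x W x 1 x N) and `targets`
#'   (N x 30 matrix).
#' @export
detector_dataset <- function(cases) {
  stopifnot(length(cases) > 0)
  imgs <- lapply(cases, function(cs) {
    if (is.null(cs$image)) stop("case ", cs$record$image_id,
                                " has no rendered image")
    cs$image
  })
  h <- nrow(imgs[[1]]); w <- ncol(imgs[[1]])
  x <- array(unlist(imgs, use.names = FALSE), c(h, w, 1L, length(imgs)))
  targets <- t(vapply(cases, function(cs) {
    pts <- get_points(cs$record, landmark_names())
    as.vector(t(cbind(pts[, "x"] / (w - 1), pts[, "y"] / (h - 1))))
  }, numeric(2L * length(landmark_names()))))
  list(images = x, targets = targets)
}

#' Train the landmark detector
#'
#' Fits the conv-regression network by mini-batch Adam on the mean squared
#' error between predicted and true normalized coordinates. Initialization,
#' data order and hence the whole loss history are deterministic in
#' `config$seed`.
#'
#' @param dataset a [detector_dataset()] (or list with `images`, `targets`).
#' @param config a [detector_config()].
#' @param detector optionally, an already built `cvm_detector` to continue
#'   training.
#' @return A trained `cvm_detector` with per-epoch `loss_history`.
#' @export
train_detector <- function(dataset, config = detector_config(),
                           detector = NULL) {
  n <- dim(dataset$images)[4]
  if (n == 0) stop("empty dataset")
  if (dim(dataset$images)[1] != config$input_height ||
      dim(dataset$images)[2] != config$input_width) {
    stop("image size does not match detector_config input size")
  }
  det <- if (is.null(detector)) build_detector(config) else detector
  det$config <- config
  state <- adam_init(det)
  set.seed(config$seed + 1L)
  history <- numeric(config$epochs)
  idx_cache <- new.env(parent = emptyenv())
  cis <- detector_conv_indices(det)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = config$batch_size)) {
      sel <- ord[start:min(start + config$batch_size - 1, n)]
      xb <- dataset$images[, , , sel, drop = FALSE]
      tb <- dataset$targets[sel, , drop = FALSE]
      fw <- detector_forward(det, xb, want_cache = TRUE,
                             idx_cache = idx_cache, cis = cis)
      loss <- mean((fw$pred - tb)^2)
      if (!is.finite(loss)) stop("non-finite training loss at epoch ", ep)
      grads <- detector_backward(det, fw, tb)
      u <- adam_update(det, grads, state, config$learning_rate, config$epsilon)
      det <- u$det
      state <- u$state
      losses <- c(losses, loss)
    }
    history[ep] <- mean(losses)
  }
  det$trained <- TRUE
  det$loss_history <- c(det$loss_history, history)
  det
}

#' @export
print.cvm_detector <- function(x, ...) {
  cfg <- x$config
  cat("<cvm_detector>", length(cfg$conv_channels), "conv layers (",
      paste(cfg$conv_channels, collapse = "-"), ") + fc ->",
      cfg$n_outputs, "coordinates\n")
  cat("  input", cfg$input_width, "x", cfg$input_height, "px;",
      if (x$trained) sprintf("trained %d epochs, final loss %.3g",
                             length(x$loss_history),
                             utils::tail(x$loss_history, 1))
      else "untrained", "\n")
  invisible(x)
}

#' @export
plot.cvm_detector <- function(x, ...) {
  if (length(x$loss_history) == 0) stop("no training history to plot")
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 xlab = "epoch", ylab = "training MSE",
                 main = "Detector training loss", ...)
  invisible(x)
}

#' Predict landmarks on new frames
#'
#' Runs the network and denormalizes the 30 outputs back to pixel
#' coordinates, assembling a full 15-landmark annotation per image.
#' Inference is deterministic.
#'
#' @param object a trained `cvm_detector`.
#' @param images a single grayscale matrix, a list of matrices, or an
#'   `H x W x 1 x N` array, matching the configured input size.
#' @param image_ids optional character ids for the returned records.
#' @param ... unused.
#' @return A single [annotation_record()] (one image) or a list of them.
#' @export
predict.cvm_detector <- function(object, images, image_ids = NULL, ...) {
  if (is.matrix(images)) images <- list(images)
  if (is.list(images)) {
    h <- nrow(images[[1]]); w <- ncol(images[[1]])
    images <- array(unlist(images, use.names = FALSE),
                    c(h, w, 1L, length(images)))
  }
  cfg <- object$config
  if (dim(images)[1] != cfg$input_height || dim(images)[2] != cfg$input_width) {
    stop("image size does not match detector_config input size")
  }
  n <- dim(images)[4]
  pred <- detector_forward(object, images)
  if (is.null(image_ids)) image_ids <- sprintf("pred_%03d", seq_len(n))
  nms <- landmark_names()
  recs <- lapply(seq_len(n), function(i) {
    v <- pred[i, ]
    xs <- v[seq(1, length(v), by = 2)] * (cfg$input_width - 1)
    ys <- v[seq(2, length(v), by = 2)] * (cfg$input_height - 1)
    annotation_record(data.frame(name = nms, x = xs, y = ys,
                                 stringsAsFactors = FALSE),
                      image_id = image_ids[i])
  })
  if (n == 1) recs[[1]] else recs
}

#' Save / load a detector checkpoint
#'
#' The checkpoint is a self-describing container (config, parameters,
#' loss history, landmark order) that reloads bit-exactly.
#'
#' @param detector a `cvm_detector`.
#' @param path checkpoint file path.
#' @return `load_detector` returns the `cvm_detector`.
#' @export
save_detector <- function(detector, path) {
  obj <- list(format = "cvmstage-detector-v1",
              landmark_order = landmark_names(), detector = detector)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "cvmstage-detector-v1")) {
    stop("not a cvmstage detector checkpoint: ", path)
  }
  obj$detector
}

#' Evaluate a detector on synthetic cases with known truth
#'
#' Predicts landmarks on each rendered case, then reports (i) per-landmark
#' placement error in mm against the ground-truth annotations (reference
#' calibration) and (ii) end-to-end staging agreement between stages derived
#' from the predicted landmarks and the true stages — the synthetic analogue
#' of a labelling-error table plus a staging metric report.
#'
#' @param detector a trained `cvm_detector`.
#' @param cases list of rendered `cvm_case` objects.
#' @param thresholds a [cvm_thresholds()] for staging.
#' @return List with `landmark_errors` (a `cvm_landmark_errors`), `staging`
#'   (a `cvm_metric_report`) and `n_unstageable` (predictions whose geometry
#'   was too degenerate to stage).
#' @export
evaluate_detector <- function(detector, cases,
                              thresholds = cvm_thresholds()) {
  imgs <- lapply(cases, function(cs) cs$image)
  ids <- vapply(cases, function(cs) cs$record$image_id, character(1))
  preds <- predict(detector, imgs, image_ids = ids)
  if (inherits(preds, "cvm_annotation")) preds <- list(preds)
  truth <- lapply(cases, function(cs) cs$record)
  errs <- landmark_errors(preds, truth)
  pred_stage <- vapply(preds, function(r) {
    tryCatch(as.character(stage_record(r, thresholds)$stage),
             error = function(e) NA_character_)
  }, character(1))
  gold <- vapply(cases, function(cs) as.character(cs$true_stage), character(1))
  ok <- !is.na(pred_stage)
  if (!any(ok)) stop("no stageable predictions")
  list(landmark_errors = errs,
       staging = metric_report(gold[ok], pred_stage[ok]),
       n_unstageable = sum(!ok))
}
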