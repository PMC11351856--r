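#' Encoder-decoder (U-Net) architecture configuration
#'
#' The network maps one 256x256 phase-contrast crop to one 256x256
#' estimated per-cell-average fluorescence crop. The encoder downsamples
#' with strided 4x4 convolutions, the decoder upsamples with 4x4 transposed
#' convolutions, 3x3 convolutions refine at every level, ReLU follows each
#' conv/deconv, and skip connections concatenate encoder features into the
#' decoder at matching resolution. Channel count at level `l` is
#' `base_channels * 2^l`. The final 3x3 convolution to one channel is
#' linear so the regression output is unconstrained.
#'
#' @param input_size Crop side in pixels (default 256; must be divisible by
#'   `2^depth`).
#' @param depth Number of resolution levels (downsamplings).
#' @param base_channels Channels at the first level. Default 16: ample for
#'   a per-cell-mean regression target, and trains at desk scale on a
#'   single CPU.
#' @param norm `"instance"` (default) applies per-channel instance
#'   normalization between each convolution and its ReLU, which
#'   substantially accelerates convergence of the pixel regression;
#'   `"none"` disables it. The final linear output convolution is never
#'   normalized.
#' @param refine Add one extra 3x3 convolution at full resolution before
#'   the output layer (default `TRUE`). The regression target is
#'   piecewise constant with sharp jumps at cell boundaries, and this is
#'   where most late-training error concentrates; the refinement layer
#'   adds capacity exactly there at ~10% extra cost.
#' @return A `network_config` object.
#' @export
network_config <- function(input_size = 256L, depth = 4L,
                           base_channels = 16L,
                           norm = c("instance", "none"),
                           refine = TRUE) {
  norm <- match.arg(norm)
  input_size <- as.integer(input_size)
  depth <- as.integer(depth)
  base_channels <- as.integer(base_channels)
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  if (input_size %% 2L^depth != 0L) {
    stop("input_size must be divisible by 2^depth", call. = FALSE)
  }
  structure(list(input_size = input_size, depth = depth,
                 base_channels = base_channels, norm = norm,
                 refine = isTRUE(refine),
                 conv_kernel = 3L, resample_kernel = 4L,
                 activation = "relu", skip_connections = TRUE),
            class = "network_config")
}

#' Training configuration
#'
#' @param optimizer_name Only `"adam"` is implemented.
#' @param learning_rate Adam step size.
#' @param batch_size Crops per gradient step.
#' @param epochs Passes over the training frames.
#' @param crops_per_image Random 256x256 crops drawn from each frame per
#'   epoch.
#' @param crop_sampling `"cell_biased"` centers crops on randomly chosen
#'   cell centroids with jitter (uniform crops of sparse fields are mostly
#'   background and stall MSE training); `"uniform"` samples crop corners
#'   uniformly.
#' @param adam_beta2 Second-moment decay of Adam (default 0.9). The
#'   pixel-regression objective is strongly non-stationary over training,
#'   and a short second-moment memory converges markedly faster here than
#'   the textbook 0.999 (which remains available).
#' @param lr_schedule `"constant"` keeps the learning rate fixed;
#'   `"cosine"` decays it to zero over the epochs (half-cosine), which
#'   helps late-stage convergence of the pixel regression.
#' @param seed Seed for the whole training run (initialization, splits,
#'   crops, shuffling); identical data + seed reproduce the run.
#' @param validation_fraction Fraction of frames held out for validation.
#'   The split is by whole frame, never by crop, so no pixels leak. With a
#'   single frame only `validation_fraction = 0` is allowed (validation
#'   then monitors the training frame).
#' @return A `train_config` object.
#' @export
train_config <- function(optimizer_name = "adam", learning_rate = 2e-3,
                         batch_size = 8L, epochs = 10L,
                         crops_per_image = 4L,
                         crop_sampling = c("cell_biased", "uniform"),
                         adam_beta2 = 0.9,
                         lr_schedule = c("constant", "cosine"),
                         seed = 1L, validation_fraction = 0.2) {
  crop_sampling <- match.arg(crop_sampling)
  lr_schedule <- match.arg(lr_schedule)
  if (adam_beta2 <= 0 || adam_beta2 >= 1) {
    stop("adam_beta2 must lie in (0, 1)", call. = FALSE)
  }
  if (optimizer_name != "adam") {
    stop("only the adam optimizer is implemented", call. = FALSE)
  }
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (validation_fraction < 0 || validation_fraction >= 1) {
    stop("validation_fraction must lie in [0, 1)", call. = FALSE)
  }
  structure(list(optimizer_name = optimizer_name,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 crops_per_image = as.integer(crops_per_image),
                 crop_sampling = crop_sampling, adam_beta2 = adam_beta2,
                 lr_schedule = lr_schedule,
                 seed = as.integer(seed),
                 validation_fraction = validation_fraction),
            class = "train_config")
}

# ---- network construction ---------------------------------------------------

conv_layer <- function(cin, cout, k, stride, pad, relu, sd, norm = FALSE) {
  l <- list(type = "conv", k = k, stride = stride, pad = pad, relu = relu,
            cin = cin, cout = cout,
            W = matrix(rnorm(k * k * cin * cout, 0, sd), k * k * cin, cout),
            b = numeric(cout))
  if (norm) {
    l$gamma <- rep(1, cout)
    l$beta <- numeric(cout)
  }
  l
}

deconv_layer <- function(cin, cout, k, stride, pad, relu, norm = FALSE) {
  sd <- sqrt(2 / (k * k * cin / stride^2))
  l <- list(type = "deconv", k = k, stride = stride, pad = pad, relu = relu,
            cin = cin, cout = cout,
            W = matrix(rnorm(k * k * cout * cin, 0, sd), k * k * cout, cin),
            b = numeric(cout))
  if (norm) {
    l$gamma <- rep(1, cout)
    l$beta <- numeric(cout)
  }
  l
}

#' Build an untrained encoder-decoder network
#'
#' @param cfg A [network_config()].
#' @param seed Seed for the (He-normal) weight initialization; a fixed seed
#'   yields identical initial weights.
#' @return A `cb_network`: config plus a named parameter list.
#' @export
build_network <- function(cfg = network_config(), seed = 1L) {
  withr::with_seed(as.integer(seed), {
    B <- cfg$base_channels
    D <- cfg$depth
    ch <- B * 2L^(0:D)
    nrm <- identical(cfg$norm, "instance")
    p <- list()
    p$c0 <- conv_layer(1L, ch[1], 3L, 1L, 1L, TRUE, sqrt(2 / 9), nrm)
    for (l in seq_len(D)) {
      p[[paste0("d", l)]] <- conv_layer(ch[l], ch[l + 1], 4L, 2L, 1L, TRUE,
                                        sqrt(2 / (16 * ch[l])), nrm)
      p[[paste0("e", l)]] <- conv_layer(ch[l + 1], ch[l + 1], 3L, 1L, 1L,
                                        TRUE, sqrt(2 / (9 * ch[l + 1])), nrm)
      p[[paste0("u", l)]] <- deconv_layer(ch[l + 1], ch[l], 4L, 2L, 1L, TRUE,
                                          nrm)
      p[[paste0("r", l)]] <- conv_layer(2L * ch[l], ch[l], 3L, 1L, 1L, TRUE,
                                        sqrt(2 / (9 * 2 * ch[l])), nrm)
    }
    if (isTRUE(cfg$refine)) {
      p$f0 <- conv_layer(ch[1], ch[1], 3L, 1L, 1L, TRUE,
                         sqrt(2 / (9 * ch[1])), nrm)
    }
    p$out <- conv_layer(ch[1], 1L, 3L, 1L, 1L, FALSE, sqrt(1 / (9 * ch[1])))
    structure(list(cfg = cfg, params = p), class = "cb_network")
  })
}

concat_ch <- function(a, b) {
  array(c(a, b), dim = c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

# One layer: conv/deconv -> (instance norm) -> (ReLU), fused in C++ with a
# float-precision cache (im2col matrix, normalized activations) handed back
# as an external pointer for the backward pass.
run_layer <- function(layer, x, ho = NULL, wo = NULL, cache = FALSE) {
  gamma <- layer$gamma %||% numeric(0)
  beta <- layer$beta %||% numeric(0)
  if (layer$type == "conv") {
    cb_layer_fwd(x, layer$W, layer$b, layer$k, layer$stride, layer$pad,
                 layer$relu, gamma, beta, cache)
  } else {
    cb_delayer_fwd(x, layer$W, layer$b, layer$k, layer$stride, layer$pad,
                   ho, wo, layer$relu, gamma, beta, cache)
  }
}

layer_bwd <- function(layer, t, gy, need_gx = TRUE) {
  gamma <- layer$gamma %||% numeric(0)
  r <- if (layer$type == "conv") {
    cb_layer_bwd(t$cache, layer$W, gamma, gy, layer$k, layer$stride,
                 layer$pad, layer$relu, need_gx)
  } else {
    cb_delayer_bwd(t$cache, layer$W, gamma, gy, layer$k, layer$stride,
                   layer$pad, layer$relu, need_gx)
  }
  g <- list(W = r$gW, b = as.numeric(r$gb))
  if (!is.null(layer$gamma)) {
    g$gamma <- as.numeric(r$gamma)
    g$beta <- as.numeric(r$beta)
  }
  list(grads = g, gx = r$gx)
}

# Forward pass; with cache = TRUE also returns the activation tape needed
# by net_backward. x is an H x W x 1 array (normalized intensities).
net_forward <- function(net, x, cache = FALSE) {
  p <- net$params
  D <- net$cfg$depth
  tape <- if (cache) new.env(parent = emptyenv()) else NULL
  run <- function(nm, xin, ho = NULL, wo = NULL) {
    r <- run_layer(p[[nm]], xin, ho, wo, cache = cache)
    if (cache) assign(nm, r, envir = tape)
    r$y
  }
  f <- vector("list", D + 1L)
  a <- run("c0", x)
  f[[1]] <- a
  h <- a
  for (l in seq_len(D)) {
    hd <- run(paste0("d", l), h)
    he <- run(paste0("e", l), hd)
    f[[l + 1L]] <- he
    h <- he
  }
  g <- f[[D + 1L]]
  for (l in rev(seq_len(D))) {
    skip <- f[[l]]
    up <- run(paste0("u", l), g, dim(skip)[1], dim(skip)[2])
    cc <- concat_ch(up, skip)
    g <- run(paste0("r", l), cc)
  }
  if (!is.null(p$f0)) g <- run("f0", g)
  y <- run("out", g)
  list(y = y, tape = tape)
}

# Backward pass given the gradient at the network output. Returns named
# gradient list matching net$params.
net_backward <- function(net, tape, gy) {
  p <- net$params
  D <- net$cfg$depth
  grads <- list()
  bwd <- function(nm, g, need_gx = TRUE) {
    r <- layer_bwd(p[[nm]], get(nm, envir = tape), g, need_gx)
    grads[[nm]] <<- r$grads
    r$gx
  }
  g <- bwd("out", gy)
  if (!is.null(p$f0)) g <- bwd("f0", g)
  gskip <- vector("list", D + 1L)
  for (l in seq_len(D)) {
    gcc <- bwd(paste0("r", l), g)
    cu <- p[[paste0("u", l)]]$cout
    gup <- gcc[, , seq_len(cu), drop = FALSE]
    gskip[[l]] <- gcc[, , cu + seq_len(dim(gcc)[3] - cu), drop = FALSE]
    g <- bwd(paste0("u", l), gup)
    # g is now the gradient at the decoder input of level l, i.e. the
    # output of r_{l+1} (or of the encoder bottleneck when l = D).
  }
  gskip[[D + 1L]] <- g
  genc <- gskip[[D + 1L]]
  for (l in rev(seq_len(D))) {
    gd <- bwd(paste0("e", l), genc)
    gf <- bwd(paste0("d", l), gd)
    genc <- gf + gskip[[l]]
  }
  bwd("c0", genc, need_gx = FALSE)
  grads
}

# ---- training ---------------------------------------------------------------

layer_param_names <- function(l) {
  intersect(c("W", "b", "gamma", "beta"), names(l))
}

adam_init <- function(params) {
  lapply(params, function(l) {
    s <- list()
    for (fld in layer_param_names(l)) {
      s[[paste0("m_", fld)]] <- l[[fld]] * 0
      s[[paste0("v_", fld)]] <- l[[fld]] * 0
    }
    s
  })
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  for (nm in names(grads)) {
    s <- state[[nm]]
    g <- grads[[nm]]
    for (fld in names(g)) {
      m <- paste0("m_", fld)
      v <- paste0("v_", fld)
      s[[m]] <- beta1 * s[[m]] + (1 - beta1) * g[[fld]]
      s[[v]] <- beta2 * s[[v]] + (1 - beta2) * g[[fld]]^2
      params[[nm]][[fld]] <- params[[nm]][[fld]] -
        lr * (s[[m]] / corr1) / (sqrt(s[[v]] / corr2) + eps)
    }
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

# Sample one crop corner (1-based top-left) for a frame.
sample_crop_corner <- function(pair, size, sampling, centroids) {
  H <- nrow(pair$phase); W <- ncol(pair$phase)
  if (sampling == "cell_biased" && !is.null(centroids) &&
      nrow(centroids) > 0L) {
    k <- sample.int(nrow(centroids), 1L)
    ci <- centroids$row[k] + 1 + round(rnorm(1, 0, 24))
    cj <- centroids$col[k] + 1 + round(rnorm(1, 0, 24))
    i <- round(ci - size / 2)
    j <- round(cj - size / 2)
  } else {
    i <- sample.int(H - size + 1L, 1L)
    j <- sample.int(W - size + 1L, 1L)
  }
  c(i = min(max(i, 1L), H - size + 1L), j = min(max(j, 1L), W - size + 1L))
}

crop_at <- function(img, corner, size) {
  img[corner[1]:(corner[1] + size - 1L), corner[2]:(corner[2] + size - 1L)]
}

#' Train the encoder-decoder on phase/target pairs
#'
#' Normalizes intensities by dataset statistics (recorded in the returned
#' model), splits frames into training and validation by whole frame,
#' minimizes mean squared error over output pixels with Adam on random
#' 256x256 crops, and retains the weights of the best-validation epoch.
#'
#' @param pairs List of [pair_for_training()] objects (>= 2 frames, unless
#'   `validation_fraction = 0`).
#' @param net_cfg A [network_config()].
#' @param train_cfg A [train_config()].
#' @param marker_name Name stored in the checkpoint.
#' @param verbose Print per-epoch losses?
#' @return A `trained_model`: network weights, both configs, normalization
#'   constants and the per-epoch training log.
#' @export
train_model <- function(pairs, net_cfg = network_config(),
                        train_cfg = train_config(),
                        marker_name = "marker1", verbose = FALSE) {
  stopifnot(length(pairs) >= 1L,
            all(vapply(pairs, inherits, TRUE, "training_pair")))
  n <- length(pairs)
  if (n < 2L && train_cfg$validation_fraction > 0) {
    stop("need >= 2 frames so a validation frame exists ",
         "(or set validation_fraction = 0)", call. = FALSE)
  }
  size <- net_cfg$input_size
  small <- vapply(pairs, function(p) {
    nrow(p$phase) < size || ncol(p$phase) < size
  }, TRUE)
  if (any(small)) {
    stop("training frames must be at least ", size, "x", size, " pixels",
         call. = FALSE)
  }

  phase_px <- unlist(lapply(pairs, function(p) as.vector(p$phase)))
  target_px <- unlist(lapply(pairs, function(p) as.vector(p$target)))
  input_norm <- list(offset = mean(phase_px),
                     scale = max(sd(phase_px), 1e-8))
  output_norm <- list(offset = mean(target_px),
                      scale = max(sd(target_px), 1e-8))

  centroids <- lapply(pairs, function(p) {
    if (is.null(p$labels)) NULL else regions_from_labelmap(p$labels)
  })

  withr::with_seed(train_cfg$seed, {
    net <- build_network(net_cfg, seed = sample.int(2^31 - 1L, 1L))
    n_val <- if (train_cfg$validation_fraction > 0) {
      max(1L, round(train_cfg$validation_fraction * n))
    } else 0L
    ord <- sample.int(n)
    val_idx <- if (n_val > 0L) ord[seq_len(n_val)] else integer(0)
    train_idx <- if (n_val > 0L) ord[-seq_len(n_val)] else ord

    # fixed validation crops, drawn once
    val_frames <- if (n_val > 0L) val_idx else train_idx
    val_crops <- purrr::map(val_frames, function(i) {
      purrr::map(seq_len(max(1L, train_cfg$crops_per_image)), function(k) {
        corner <- sample_crop_corner(pairs[[i]], size,
                                     train_cfg$crop_sampling,
                                     centroids[[i]])
        list(x = norm_input(pairs[[i]]$phase, corner, size, input_norm),
             t = norm_target(pairs[[i]]$target, corner, size, output_norm))
      })
    })
    val_crops <- purrr::flatten(val_crops)

    state <- adam_init(net$params)
    step <- 0L
    log <- vector("list", train_cfg$epochs)
    best_val <- Inf
    best_params <- net$params
    for (epoch in seq_len(train_cfg$epochs)) {
      lr_epoch <- if (train_cfg$lr_schedule == "cosine") {
        train_cfg$learning_rate * 0.5 *
          (1 + cos(pi * (epoch - 1) / train_cfg$epochs))
      } else {
        train_cfg$learning_rate
      }
      crop_queue <- list()
      for (i in sample(train_idx)) {
        for (k in seq_len(train_cfg$crops_per_image)) {
          corner <- sample_crop_corner(pairs[[i]], size,
                                       train_cfg$crop_sampling,
                                       centroids[[i]])
          crop_queue[[length(crop_queue) + 1L]] <- list(frame = i,
                                                        corner = corner)
        }
      }
      losses <- numeric(0)
      batch_starts <- seq(1L, length(crop_queue), by = train_cfg$batch_size)
      for (bi in seq_along(batch_starts)) {
        b0 <- batch_starts[bi]
        batch <- crop_queue[b0:min(b0 + train_cfg$batch_size - 1L,
                                   length(crop_queue))]
        acc <- NULL
        bloss <- 0
        for (cr in batch) {
          x <- norm_input(pairs[[cr$frame]]$phase, cr$corner, size,
                          input_norm)
          t <- norm_target(pairs[[cr$frame]]$target, cr$corner, size,
                           output_norm)
          fw <- net_forward(net, x, cache = TRUE)
          resid <- fw$y - t
          loss <- mean(resid^2)
          if (!is.finite(loss)) {
            stop(sprintf(
              "NaN/Inf loss at epoch %d, batch %d (frame %d, crop at %d,%d)",
              epoch, bi, cr$frame, cr$corner[1], cr$corner[2]),
              call. = FALSE)
          }
          bloss <- bloss + loss
          gy <- 2 * resid / length(resid)
          g <- net_backward(net, fw$tape, gy)
          acc <- if (is.null(acc)) g else accumulate_grads(acc, g)
        }
        acc <- scale_grads(acc, 1 / length(batch))
        step <- step + 1L
        upd <- adam_step(net$params, acc, state, lr_epoch, step,
                         beta2 = train_cfg$adam_beta2)
        net$params <- upd$params
        state <- upd$state
        losses <- c(losses, bloss / length(batch))
      }
      val_mse <- mean(vapply(val_crops, function(cr) {
        mean((net_forward(net, cr$x)$y - cr$t)^2)
      }, numeric(1)))
      log[[epoch]] <- tibble::tibble(epoch = epoch,
                                     train_mse = mean(losses),
                                     val_mse = val_mse)
      if (val_mse <= best_val) {
        best_val <- val_mse
        best_params <- net$params
      }
      if (verbose) {
        message(sprintf("epoch %3d  train %.5g  val %.5g", epoch,
                        mean(losses), val_mse))
      }
    }
    net$params <- best_params
    structure(list(net = net, net_cfg = net_cfg, train_cfg = train_cfg,
                   input_norm = input_norm, output_norm = output_norm,
                   marker_name = marker_name,
                   training_log = dplyr::bind_rows(log)),
              class = "trained_model")
  })
}

norm_input <- function(img, corner, size, norm) {
  x <- normalize_intensity(crop_at(img, corner, size), norm)
  array(x, dim = c(size, size, 1L))
}

norm_target <- function(img, corner, size, norm) {
  t <- normalize_intensity(crop_at(img, corner, size), norm)
  array(t, dim = c(size, size, 1L))
}

accumulate_grads <- function(a, g) {
  for (nm in names(g)) {
    for (fld in names(g[[nm]])) {
      a[[nm]][[fld]] <- a[[nm]][[fld]] + g[[nm]][[fld]]
    }
  }
  a
}

scale_grads <- function(a, s) {
  for (nm in names(a)) {
    for (fld in names(a[[nm]])) {
      a[[nm]][[fld]] <- a[[nm]][[fld]] * s
    }
  }
  a
}

#' @export
print.trained_model <- function(x, ...) {
  cat("<trained_model> marker '", x$marker_name, "', depth ",
      x$net_cfg$depth, ", base ", x$net_cfg$base_channels, " channels\n",
      sep = "")
  if (nrow(x$training_log)) {
    best <- which.min(x$training_log$val_mse)
    cat("  best validation MSE ",
        signif(x$training_log$val_mse[best], 4), " at epoch ", best,
        " of ", nrow(x$training_log), "\n", sep = "")
  }
  invisible(x)
}

#' @export
glance.trained_model <- function(x, ...) {
  lg <- x$training_log
  tibble::tibble(marker = x$marker_name,
                 epochs = nrow(lg),
                 best_epoch = if (nrow(lg)) which.min(lg$val_mse) else NA_integer_,
                 train_mse = if (nrow(lg)) lg$train_mse[nrow(lg)] else NA_real_,
                 val_mse = if (nrow(lg)) min(lg$val_mse) else NA_real_,
                 n_parameters = sum(vapply(x$net$params, function(l) {
                   sum(lengths(l[layer_param_names(l)]))
                 }, numeric(1))))
}

#' @export
tidy.trained_model <- function(x, ...) x$training_log

#' Training-curve plot for a trained model
#' @param object A `trained_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trained_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$training_log, c("train_mse", "val_mse"),
                            names_to = "split", values_to = "mse")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$mse,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "MSE (normalized intensities)")
}

# ---- inference --------------------------------------------------------------

#' Predict a full-field fluorescence estimate from a phase image
#'
#' Fields larger than one crop are assembled from overlapping 256x256
#' tiles (50% overlap) blended with a raised-cosine window; blending
#' weights are normalized so they sum to 1 at every pixel. A single-tile
#' input reduces to the raw forward pass. Output is in the original
#' intensity units.
#'
#' @param object A `trained_model`.
#' @param phase Phase-contrast matrix, at least 256x256.
#' @param ... Unused.
#' @return Numeric matrix of the same dimensions as `phase`.
#' @export
predict.trained_model <- function(object, phase, ...) {
  size <- object$net_cfg$input_size
  H <- nrow(phase); W <- ncol(phase)
  if (H < size || W < size) {
    stop("image is smaller than one ", size, "x", size,
         " tile; pad it before prediction", call. = FALSE)
  }
  stride <- size %/% 2L
  starts <- function(n) {
    s <- seq(1L, n - size + 1L, by = stride)
    if (tail(s, 1L) != n - size + 1L) s <- c(s, n - size + 1L)
    s
  }
  w1 <- 0.5 - 0.5 * cos(2 * pi * (seq_len(size) - 0.5) / size) + 1e-3
  w2 <- outer(w1, w1)
  acc <- matrix(0, H, W)
  wsum <- matrix(0, H, W)
  for (i in starts(H)) {
    for (j in starts(W)) {
      x <- normalize_intensity(phase[i:(i + size - 1L), j:(j + size - 1L)],
                               object$input_norm)
      y <- net_forward(object$net, array(x, c(size, size, 1L)))$y[, , 1L]
      ri <- i:(i + size - 1L); rj <- j:(j + size - 1L)
      acc[ri, rj] <- acc[ri, rj] + y * w2
      wsum[ri, rj] <- wsum[ri, rj] + w2
    }
  }
  denormalize_intensity(acc / wsum, object$output_norm)
}

#' Estimate per-cell marker levels from a phase image
#'
#' Composition of [predict.trained_model()] and [measure_cell_means()] over
#' the provided label map.
#'
#' @param model A `trained_model`.
#' @param phase Phase-contrast matrix.
#' @param labels A [label_map][as_label_map].
#' @return Tibble `cell_id`, `estimate`.
#' @export
estimate_cell_levels <- function(model, phase, labels) {
  labels <- as_label_map(labels)
  if (n_regions(labels) == 0L) {
    return(tibble::tibble(cell_id = integer(), estimate = numeric()))
  }
  est <- predict(model, phase)
  dplyr::rename(measure_cell_means(est, labels), estimate = "mean")
}

# ---- checkpoints ------------------------------------------------------------

#' Save a trained model to a single JSON checkpoint
#'
#' The checkpoint is human-readable and self-contained: weights, both
#' configs, intensity-normalization constants, marker name and training
#' log. Numbers are written at full precision, so save/load round-trips to
#' bit-identical predictions.
#'
#' @param model A `trained_model`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  # weights are base64-encoded IEEE doubles so the round trip is
  # bit-exact; everything else stays plain, readable JSON
  layers <- purrr::map(model$net$params, function(l) {
    out <- list(type = l$type, k = l$k, stride = l$stride, pad = l$pad,
                relu = l$relu, cin = l$cin, cout = l$cout,
                W = jsonlite::base64_enc(writeBin(as.vector(l$W), raw())),
                Wdim = dim(l$W),
                b = jsonlite::base64_enc(writeBin(as.vector(l$b), raw())))
    if (!is.null(l$gamma)) {
      out$gamma <- jsonlite::base64_enc(writeBin(as.vector(l$gamma), raw()))
      out$beta <- jsonlite::base64_enc(writeBin(as.vector(l$beta), raw()))
    }
    out
  })
  obj <- list(format = "cellbright-checkpoint-1",
              marker_name = model$marker_name,
              net_cfg = unclass(model$net_cfg),
              train_cfg = unclass(model$train_cfg),
              input_norm = model$input_norm,
              output_norm = model$output_norm,
              training_log = model$training_log,
              layers = layers)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Load a checkpoint written by [save_model()]
#' @param path Path to the `.json` checkpoint.
#' @return A `trained_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cellbright-checkpoint-1")) {
    stop("not a cellbright checkpoint: ", path, call. = FALSE)
  }
  net_cfg <- structure(obj$net_cfg, class = "network_config")
  train_cfg <- structure(obj$train_cfg, class = "train_config")
  params <- purrr::map(obj$layers, function(l) {
    w <- readBin(jsonlite::base64_dec(l$W), numeric(),
                 n = prod(l$Wdim))
    b <- readBin(jsonlite::base64_dec(l$b), numeric(), n = l$cout)
    out <- list(type = l$type, k = l$k, stride = l$stride, pad = l$pad,
                relu = l$relu, cin = l$cin, cout = l$cout,
                W = matrix(w, l$Wdim[1], l$Wdim[2]), b = b)
    if (!is.null(l$gamma)) {
      out$gamma <- readBin(jsonlite::base64_dec(l$gamma), numeric(),
                           n = l$cout)
      out$beta <- readBin(jsonlite::base64_dec(l$beta), numeric(),
                          n = l$cout)
    }
    out
  })
  structure(list(net = structure(list(cfg = net_cfg, params = params),
                                 class = "cb_network"),
                 net_cfg = net_cfg, train_cfg = train_cfg,
                 input_norm = obj$input_norm, output_norm = obj$output_norm,
                 marker_name = obj$marker_name,
                 training_log = tibble::as_tibble(obj$training_log)),
            class = "trained_model")
}
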