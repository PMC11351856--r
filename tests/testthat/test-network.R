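# Pure-R reference convolution (independent oracle for the C++ layers).
conv_ref <- function(x, W, b, k, s, p) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; C <- dim(x)[3]
  Ho <- (H + 2 * p - k) %/% s + 1
  Wo <- (Wd + 2 * p - k) %/% s + 1
  Cout <- length(b)
  y <- array(0, c(Ho, Wo, Cout))
  for (io in 1:Ho) for (jo in 1:Wo) {
    patch <- numeric(k * k * C)
    for (c in 1:C) for (di in 0:(k - 1)) for (dj in 0:(k - 1)) {
      i <- (io - 1) * s - p + di + 1
      j <- (jo - 1) * s - p + dj + 1
      v <- if (i >= 1 && i <= H && j >= 1 && j <= Wd) x[i, j, c] else 0
      patch[((c - 1) * k + di) * k + dj + 1] <- v
    }
    for (co in 1:Cout) y[io, jo, co] <- sum(patch * W[, co]) + b[co]
  }
  y
}

test_that("convolution layers match a pure-R reference", {
  withr::local_seed(42)
  x <- array(rnorm(10 * 12 * 3), c(10, 12, 3))
  W3 <- matrix(rnorm(27 * 2), 27, 2)
  W4 <- matrix(rnorm(48 * 2), 48, 2)
  b <- rnorm(2)
  expect_equal(cellbright:::cb_conv_fwd(x, W3, b, 3L, 1L, 1L, FALSE),
               conv_ref(x, W3, b, 3, 1, 1), tolerance = 1e-5)
  expect_equal(cellbright:::cb_conv_fwd(x, W4, b, 4L, 2L, 1L, FALSE),
               conv_ref(x, W4, b, 4, 2, 1), tolerance = 1e-5)
})

test_that("transposed convolution is the exact adjoint of convolution", {
  withr::local_seed(43)
  # <deconv(x), y> == <x, conv(y)> for shared weights
  x <- array(rnorm(4 * 4 * 5), c(4, 4, 5))
  y <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  W <- matrix(rnorm(16 * 3 * 5), 48, 5)
  up <- cellbright:::cb_deconv_fwd(x, W, rep(0, 3), 4L, 2L, 1L, 8L, 8L,
                                   FALSE)
  down <- cellbright:::cb_conv_fwd(y, W, rep(0, 5), 4L, 2L, 1L, FALSE)
  expect_equal(sum(up * y), sum(down * x), tolerance = 1e-4)
})

test_that("analytic gradients agree with finite differences", {
  withr::local_seed(44)
  cfg <- network_config(input_size = 32L, depth = 2L, base_channels = 4L)
  net <- build_network(cfg, seed = 3L)
  x <- array(rnorm(32 * 32), c(32, 32, 1))
  t <- array(rnorm(32 * 32), c(32, 32, 1))
  loss_of <- function(n) mean((cellbright:::net_forward(n, x)$y - t)^2)
  fw <- cellbright:::net_forward(net, x, cache = TRUE)
  g <- cellbright:::net_backward(net, fw$tape, 2 * (fw$y - t) / length(t))
  checked <- 0L
  for (nm in c("d1", "u1", "r2", "out")) {
    for (ii in sample(length(net$params[[nm]]$W), 2L)) {
      eps <- 1e-2
      np <- nm2 <- net
      np$params[[nm]]$W[ii] <- np$params[[nm]]$W[ii] + eps
      nm2$params[[nm]]$W[ii] <- nm2$params[[nm]]$W[ii] - eps
      num <- (loss_of(np) - loss_of(nm2)) / (2 * eps)
      ana <- g[[nm]]$W[ii]
      # single-precision forward + ReLU kinks limit attainable agreement
      expect_equal(ana, num, tolerance = 0.15)
      checked <- checked + 1L
    }
  }
  expect_identical(checked, 8L)
})

test_that("output shape equals input shape across depths", {
  for (depth in c(3L, 4L)) {
    cfg <- network_config(input_size = 64L, depth = depth,
                          base_channels = 4L)
    net <- build_network(cfg, seed = 1L)
    y <- cellbright:::net_forward(net, array(rnorm(64 * 64),
                                             c(64, 64, 1)))$y
    expect_identical(dim(y), c(64L, 64L, 1L))
  }
})

test_that("a zero final layer yields an all-zero output", {
  net <- build_network(network_config(input_size = 32L, depth = 1L,
                                      base_channels = 2L), seed = 2L)
  net$params$out$W[] <- 0
  net$params$out$b[] <- 0
  y <- cellbright:::net_forward(net, array(runif(32 * 32), c(32, 32, 1)))$y
  expect_true(all(y == 0))
})

test_that("a fixed seed reproduces identical initial weights", {
  cfg <- network_config(input_size = 32L, depth = 2L, base_channels = 4L)
  expect_identical(build_network(cfg, seed = 9L)$params,
                   build_network(cfg, seed = 9L)$params)
  expect_false(identical(build_network(cfg, seed = 9L)$params,
                         build_network(cfg, seed = 10L)$params))
})

test_that("training converges to a constant for constant targets", {
  withr::local_seed(20)
  pairs <- lapply(1:2, function(i) {
    pair_for_training(matrix(runif(64 * 64), 64, 64),
                      matrix(0.37, 64, 64))
  })
  m <- train_model(pairs,
                   network_config(input_size = 32L, depth = 1L,
                                  base_channels = 2L),
                   train_config(epochs = 3L, crops_per_image = 2L,
                                batch_size = 2L, seed = 5L,
                                validation_fraction = 0.5),
                   marker_name = "const")
  pred <- predict(m, matrix(runif(64 * 64), 64, 64))
  expect_lt(max(abs(pred - 0.37)), 0.05)
})

test_that("training is deterministic given data and seed", {
  withr::local_seed(21)
  fr <- generate_frame(tiny_spec(n_cells = 4L, width = 256L, height = 256L,
                                 cell_radius_mean = 18))
  tg <- build_target(fr$markers$marker1, fr$truth_labels)
  pairs <- list(pair_for_training(fr$phase, tg),
                pair_for_training(fr$phase, tg))
  args <- list(pairs,
               network_config(input_size = 64L, depth = 2L,
                              base_channels = 4L),
               train_config(epochs = 2L, crops_per_image = 2L,
                            batch_size = 2L, seed = 12L,
                            validation_fraction = 0.5))
  m1 <- do.call(train_model, args)
  m2 <- do.call(train_model, args)
  expect_identical(m1$training_log, m2$training_log)
  expect_identical(m1$net$params, m2$net$params)
})

test_that("training refuses a single frame when validation is requested", {
  pair <- pair_for_training(matrix(runif(256^2), 256, 256),
                            matrix(0, 256, 256))
  expect_error(train_model(list(pair), train_cfg = train_config()),
               ">= 2 frames")
})

test_that("checkpoints round-trip to identical predictions", {
  withr::local_seed(22)
  m <- constant_model(0.4)
  # make it non-trivial: random final layer
  m$net$params$out$W[] <- rnorm(length(m$net$params$out$W), 0, 0.1)
  m$net$params$out$b[] <- 0.05
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  x <- matrix(runif(64 * 64), 64, 64)
  expect_identical(predict(m, x), predict(back, x))
  expect_identical(back$marker_name, m$marker_name)
  expect_equal(back$input_norm, m$input_norm)
})

test_that("tiled prediction reduces to the raw forward pass on one tile", {
  withr::local_seed(23)
  m <- constant_model(0)
  m$net$params$out$W[] <- rnorm(length(m$net$params$out$W), 0, 0.1)
  x <- matrix(runif(64 * 64), 64, 64)
  direct <- cellbright:::net_forward(m$net, array(x, c(64, 64, 1)))$y[, , 1]
  expect_equal(predict(m, x), direct, tolerance = 1e-12)
})

test_that("tiled prediction covers larger fields consistently", {
  withr::local_seed(24)
  m <- constant_model(0.4)
  # constant model: blending any number of tiles must reproduce the
  # constant exactly everywhere (weights sum to 1 after normalization)
  pred <- predict(m, matrix(runif(160 * 96), 160, 96))
  expect_identical(dim(pred), c(160L, 96L))
  expect_equal(as.vector(pred), rep(0.4, 160 * 96), tolerance = 1e-6)
  expect_error(predict(m, matrix(0, 32, 32)), "smaller than")
})

test_that("periodic inputs give translation-consistent tile interiors", {
  withr::local_seed(25)
  m <- constant_model(0)
  m$net$params$out$W[] <- rnorm(length(m$net$params$out$W), 0, 0.1)
  base <- matrix(runif(64 * 64), 64, 64)
  big <- rbind(cbind(base, base, base), cbind(base, base, base))
  pred <- predict(m, big)  # 128 x 192, stride 32
  # one full period apart (64 px): central interior rows must match
  expect_equal(pred[33:96, 65:96], pred[33:96, 129:160], tolerance = 1e-4)
})

test_that("per-cell estimates compose prediction and region means", {
  fr <- generate_frame(tiny_spec(n_cells = 5L))
  m <- constant_model(0.4, input_size = 64L)
  est <- estimate_cell_levels(m, fr$phase, fr$truth_labels)
  expect_identical(nrow(est), n_regions(fr$truth_labels))
  expect_equal(est$estimate, rep(0.4, nrow(est)), tolerance = 1e-6)
  empty <- estimate_cell_levels(m, fr$phase,
                                as_label_map(matrix(0L, 320, 320)))
  expect_identical(nrow(empty), 0L)
})

test_that("model summaries expose the training log", {
  m <- constant_model(0.1)
  m$training_log <- tibble::tibble(epoch = 1:3,
                                   train_mse = c(1, 0.5, 0.2),
                                   val_mse = c(1.1, 0.6, 0.4))
  g <- glance(m)
  expect_identical(g$best_epoch, 3L)
  expect_identical(tidy(m), m$training_log)
})
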