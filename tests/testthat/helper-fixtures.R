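# Shared fixtures: everything is generated in code at test time.

tiny_spec <- function(...) {
  args <- list(width = 320L, height = 320L, n_cells = 10L,
               cell_radius_mean = 22, cell_radius_sd = 3,
               noise_sd = 0, seed = 1L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(scene_spec, args)
}

# A trained_model that predicts a constant everywhere, with identity
# normalization: exercises composition paths without any training.
constant_model <- function(value, input_size = 64L) {
  net <- build_network(network_config(input_size = input_size, depth = 2L,
                                      base_channels = 4L), seed = 1L)
  net$params$out$W[] <- 0
  net$params$out$b[] <- value
  structure(list(net = net, net_cfg = net$cfg, train_cfg = train_config(),
                 input_norm = list(offset = 0, scale = 1),
                 output_norm = list(offset = 0, scale = 1),
                 marker_name = "marker1",
                 training_log = tibble::tibble(epoch = integer(),
                                               train_mse = numeric(),
                                               val_mse = numeric())),
            class = "trained_model")
}

# Brute-force BFS connected-component labeling (independent oracle).
bfs_label <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 4L) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    as.matrix(expand.grid(-1:1, -1:1))[-5, ]
  }
  cur <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        ii <- p[1] + nb[k, 1]; jj <- p[2] + nb[k, 2]
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# Brute-force per-region means (independent oracle for measure_cell_means).
brute_means <- function(image, labmat) {
  ids <- sort(unique(labmat[labmat > 0L]))
  vapply(ids, function(id) mean(image[labmat == id]), numeric(1))
}

# Random label map from stamped rectangles (later stamps overwrite earlier).
random_labelmap <- function(H, W, k = 4L) {
  m <- matrix(0L, H, W)
  for (id in seq_len(k)) {
    h <- sample.int(max(2L, H %/% 2L), 1L) + 1L
    w <- sample.int(max(2L, W %/% 2L), 1L) + 1L
    i <- sample.int(H - h + 1L, 1L)
    j <- sample.int(W - w + 1L, 1L)
    m[i:(i + h - 1L), j:(j + w - 1L)] <- id
  }
  m
}
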