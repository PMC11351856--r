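test_that("an empty scene has no regions and background membrane", {
  fr <- generate_frame(tiny_spec(n_cells = 0L))
  expect_identical(n_regions(fr$truth_labels), 0L)
  expect_equal(max(fr$membrane), fr$spec$background_level, tolerance = 1e-12)
  expect_identical(nrow(fr$truth_levels), 0L)
})

test_that("identical specs regenerate bit-identical frames", {
  sp <- tiny_spec(n_cells = 5L, seed = 7L, noise_sd = 0.02)
  a <- generate_frame(sp)
  b <- generate_frame(sp)
  expect_identical(a$phase, b$phase)
  expect_identical(a$membrane, b$membrane)
  expect_identical(a$markers, b$markers)
  expect_identical(a$truth_labels$labels, b$truth_labels$labels)
  expect_identical(a$truth_levels, b$truth_levels)
})

test_that("zero-weight link with intercept gives exact per-cell means", {
  sp <- tiny_spec(texture_amplitude = 0, noise_sd = 0,
                  marker_links = list(marker_link(
                    marker_name = "m", weights = c(area = 0),
                    intercept = 10, noise_sd = 0)))
  fr <- generate_frame(sp)
  means <- measure_cell_means(fr$markers$m, fr$truth_labels)
  expect_equal(means$mean, rep(10, n_regions(fr$truth_labels)))
})

test_that("truth levels match per-region image means when noiseless", {
  fr <- generate_frame(tiny_spec(seed = 3L))
  means <- measure_cell_means(fr$markers$marker1, fr$truth_labels)
  truth <- fr$truth_levels[match(means$cell_id, fr$truth_levels$cell_id), ]
  expect_equal(means$mean, truth$level, tolerance = 1e-6)
})

test_that("membrane is at least 4x background exactly on footprints", {
  fr <- generate_frame(tiny_spec(seed = 2L))
  bg <- fr$spec$background_level
  on <- fr$truth_labels$labels > 0L
  expect_true(all(fr$membrane[on] >= 4 * bg))
  expect_true(all(fr$membrane[!on] <= bg + 1e-12))
})

test_that("cell footprints are disjoint and 8-disconnected from each other", {
  fr <- generate_frame(tiny_spec(n_cells = 12L, seed = 9L))
  lab <- fr$truth_labels$labels
  H <- nrow(lab); W <- ncol(lab)
  # neighboring pixels (any of the 8 directions) never carry two
  # different nonzero ids
  for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    ia <- seq_len(H - abs(sh[1]))
    ja <- if (sh[2] >= 0L) seq_len(W - sh[2]) else seq_len(W + sh[2]) - sh[2]
    a <- lab[ia, ja, drop = FALSE]
    b <- lab[ia + abs(sh[1]), ja + sh[2], drop = FALSE]
    both <- a > 0L & b > 0L
    expect_true(all(a[both] == b[both]))
  }
})

test_that("impossible packings raise an explicit error", {
  expect_error(
    generate_frame(scene_spec(width = 256L, height = 256L, n_cells = 200L,
                              cell_radius_mean = 30, cell_radius_sd = 1,
                              seed = 1L)),
    "impossible packing")
})

test_that("static time-lapse reproduces labels across frames", {
  tsp <- timelapse_spec(base = tiny_spec(n_cells = 6L), n_frames = 2L,
                        motion_sd = 0, density_growth = 0L)
  tl <- generate_timelapse(tsp)
  expect_identical(tl$frames[[1]]$truth_labels$labels,
                   tl$frames[[2]]$truth_labels$labels)
})

test_that("damage transient spikes at the event frame and cell is removed", {
  sp <- tiny_spec(n_cells = 6L,
                  marker_links = list(marker_link(
                    marker_name = "p53like", weights = c(area = 0.1),
                    intercept = 0.2, dynamics = "damage_transient",
                    half_life = 2, spike = 0.5)))
  tsp <- timelapse_spec(base = sp, n_frames = 6L, motion_sd = 0,
                        rupture_events = data.frame(cell_id = 3L, frame = 4L),
                        rupture_lag = 1L)
  tl <- generate_timelapse(tsp)
  lvl <- function(f) {
    x <- tl$frames[[f]]$truth_levels
    x$level[x$cell_id == 3L]
  }
  expect_gt(lvl(4), lvl(3))
  # decays while persisting, gone after the lag
  expect_lt(lvl(5), lvl(4))
  expect_false(3L %in% tl$frames[[6]]$truth_cells$cell_id)
  expect_true(3L %in% tl$frames[[5]]$truth_cells$cell_id)
})

test_that("rupture naming an unknown cell id errors", {
  tsp <- timelapse_spec(base = tiny_spec(n_cells = 3L), n_frames = 3L,
                        rupture_events = data.frame(cell_id = 99L,
                                                    frame = 2L))
  expect_error(generate_timelapse(tsp), "nonexistent cell id")
})

test_that("density growth raises density-linked truth levels", {
  sp <- tiny_spec(n_cells = 5L, seed = 21L,
                  marker_links = list(
                    marker_link("up", weights = c(area = 0),
                                intercept = 0.2, dynamics = "density_up",
                                density_gain = 1500),
                    marker_link("down", weights = c(area = 0),
                                intercept = 0.6, dynamics = "density_down",
                                density_gain = 1500)))
  tsp <- timelapse_spec(base = sp, n_frames = 8L, motion_sd = 1,
                        density_growth = 3L)
  tl <- generate_timelapse(tsp)
  truth <- timelapse_truth(tl)
  per_frame <- dplyr::summarise(
    dplyr::group_by(truth, .data$frame, .data$marker),
    n = dplyr::n_distinct(.data$cell_id),
    level = mean(.data$estimate), .groups = "drop")
  up <- per_frame[per_frame$marker == "up", ]
  down <- per_frame[per_frame$marker == "down", ]
  expect_gt(stats::cor(up$n, up$level), 0)
  expect_lt(stats::cor(down$n, down$level), 0)
})
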