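static_timelapse <- function(n_frames = 4L, n_cells = 6L, seed = 31L) {
  generate_timelapse(timelapse_spec(
    base = tiny_spec(n_cells = n_cells, seed = seed),
    n_frames = n_frames, motion_sd = 0, density_growth = 0L))
}

test_that("a single frame reduces to estimate_cell_levels", {
  fr <- generate_frame(tiny_spec(n_cells = 5L))
  m <- constant_model(0.25, input_size = 64L)
  seg <- segmentation_config(opening_radius = 0L)
  tab <- run_timelapse(list(fr), list(marker1 = m), seg)
  lab <- binarize_and_label(fr$membrane, seg)
  direct <- estimate_cell_levels(m, fr$phase, lab)
  expect_identical(nrow(tab), nrow(direct))
  expect_equal(sort(tab$estimate), sort(direct$estimate))
  expect_true(all(tab$frame == 1L))
})

test_that("k frames x m markers x c cells produce k*m*c rows", {
  tl <- static_timelapse(n_frames = 3L, n_cells = 4L)
  models <- list(a = constant_model(0.2, 64L), b = constant_model(0.6, 64L))
  tab <- run_timelapse(tl$frames, models,
                       segmentation_config(opening_radius = 0L))
  expect_identical(nrow(tab), 3L * 2L * 4L)
  expect_identical(attr(tab, "failed_frames"), integer(0))
})

test_that("frames that segment to nothing are recorded and skipped", {
  fr <- generate_frame(tiny_spec(n_cells = 3L))
  blank <- fr
  blank$membrane <- matrix(0, 320, 320)
  m <- list(marker1 = constant_model(0.2, 64L))
  expect_warning(
    expect_warning(
      tab <- run_timelapse(list(fr, blank), m,
                           segmentation_config(opening_radius = 0L)),
      "constant image"),
    "frame")
  expect_identical(attr(tab, "failed_frames"), 2L)
  expect_true(all(tab$frame == 1L))
})

test_that("static scenes link into one full-length track per cell", {
  tl <- static_timelapse(n_frames = 5L, n_cells = 6L)
  tab <- timelapse_truth(tl)
  traj <- link_trajectories(tab)
  expect_identical(dplyr::n_distinct(traj$track_id), 6L)
  spans <- dplyr::summarise(dplyr::group_by(traj, .data$track_id),
                            n = dplyr::n_distinct(.data$frame),
                            .groups = "drop")
  expect_true(all(spans$n == 5L))
  expect_false(any(traj$ambiguous))
})

test_that("a ruptured cell's trajectory ends at its rupture frame", {
  sp <- tiny_spec(n_cells = 6L, seed = 33L)
  tl <- generate_timelapse(timelapse_spec(
    base = sp, n_frames = 6L, motion_sd = 0,
    rupture_events = data.frame(cell_id = 2L, frame = 3L)))
  tab <- timelapse_truth(tl)
  traj <- link_trajectories(tab)
  # the generator removes cell 2 after frame 3: its track must stop there
  ends <- dplyr::summarise(dplyr::group_by(traj, .data$track_id),
                           last = max(.data$frame), .groups = "drop")
  expect_identical(sort(ends$last), c(3L, rep(6L, 5)))
})

test_that("two cells crossing within the gate resolve by displacement", {
  # toy detections: two cells approach and pass within the gate
  tab <- tibble::tibble(
    frame = rep(1:3, each = 2),
    cell_id = rep(1:2, times = 3),
    row = c(10, 40, 20, 30, 30, 20),
    col = rep(10, 6),
    area = 50L, marker = "m",
    estimate = c(1, 2, 1, 2, 1, 2))
  traj <- link_trajectories(tab, gate = 30)
  expect_identical(dplyr::n_distinct(traj$track_id), 2L)
  # minimal total displacement: where the paths meet, each track keeps
  # the nearest detection (identities swap at the crossing), and the
  # ambiguous encounter is flagged
  t1 <- sort(traj$row[traj$track_id == traj$track_id[traj$frame == 1 &
                                                       traj$row == 10]])
  expect_identical(t1, c(10, 20, 20))
  expect_true(any(traj$ambiguous[traj$frame > 1]))
})

test_that("density analysis recovers programmed signs from truth levels", {
  sp <- tiny_spec(
    n_cells = 5L, seed = 35L,
    marker_links = list(
      marker_link("up", weights = c(area = 0), intercept = 0.2,
                  dynamics = "density_up", density_gain = 1500),
      marker_link("down", weights = c(area = 0), intercept = 0.6,
                  dynamics = "density_down", density_gain = 1500),
      marker_link("flat", weights = c(area = 0), intercept = 0.4)))
  tl <- generate_timelapse(timelapse_spec(base = sp, n_frames = 8L,
                                          motion_sd = 1,
                                          density_growth = 3L))
  truth <- timelapse_truth(tl)
  up <- density_analysis(truth, "up")
  down <- density_analysis(truth, "down")
  expect_gt(up$result$r, 0)
  expect_lt(down$result$r, 0)
  expect_identical(nrow(up$per_frame), 8L)
  # a constant marker has an undefined correlation against density
  expect_error(density_analysis(truth, "flat"), "constant")
})

test_that("density analysis needs at least three frames", {
  tl <- static_timelapse(n_frames = 2L)
  expect_error(density_analysis(timelapse_truth(tl), "marker1"),
               ">= 3 frames")
})

test_that("event response exceeds 1 for transients and is ~1 for static", {
  sp <- tiny_spec(
    n_cells = 6L, seed = 36L,
    marker_links = list(
      marker_link("p53like", weights = c(area = 0), intercept = 0.3,
                  dynamics = "damage_transient", half_life = 2,
                  spike = 0.5),
      marker_link("flat", weights = c(area = 0), intercept = 0.4)))
  events_gen <- data.frame(cell_id = c(2L, 5L), frame = c(4L, 5L))
  tl <- generate_timelapse(timelapse_spec(base = sp, n_frames = 8L,
                                          motion_sd = 0,
                                          rupture_events = events_gen,
                                          rupture_lag = 2L))
  truth <- timelapse_truth(tl)
  traj <- link_trajectories(truth)
  # map generator cell ids to track ids via frame-1 identity (static scene)
  first <- traj[traj$frame == 1L & traj$marker == "p53like", ]
  ev <- data.frame(track_id = first$track_id[match(events_gen$cell_id,
                                                   first$cell_id)],
                   frame = events_gen$frame)
  resp <- event_response(traj, ev, "p53like", window = 2L)
  expect_true(all(resp$response_ratio > 1))
  null <- event_response(traj, ev, "flat", window = 2L)
  expect_equal(null$response_ratio, rep(1, 2), tolerance = 1e-9)
  expect_error(event_response(traj, data.frame(track_id = 999L, frame = 2L),
                              "flat"),
               "unknown track")
})
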