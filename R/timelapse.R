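#' Apply trained models frame-by-frame to a time-lapse sequence
#'
#' For each frame: segment the membrane channel, then estimate per-cell
#' levels for every marker model. A frame whose segmentation fails (or
#' finds no cells) is recorded as missing and the run continues.
#'
#' @param frames List of frame objects with `phase` and `membrane`
#'   matrices (e.g. `scene_frame`s or a `timelapse$frames` list).
#' @param models Named list of `trained_model`s, one per marker.
#' @param seg A [segmentation_config()].
#' @return Tibble keyed by (`frame`, `cell_id`, `marker`): `row`, `col`
#'   (0-based centroid), `area`, `estimate`. Skipped frames are absent;
#'   their indices are attached as attribute `"failed_frames"`.
#' @export
run_timelapse <- function(frames, models, seg = segmentation_config()) {
  stopifnot(length(frames) >= 1L, length(models) >= 1L)
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- vapply(models, function(m) m$marker_name, character(1))
  }
  failed <- integer(0)
  rows <- purrr::imap(frames, function(fr, f) {
    labels <- tryCatch(binarize_and_label(fr$membrane, seg),
                       error = function(e) NULL)
    if (is.null(labels) || n_regions(labels) == 0L) {
      failed <<- c(failed, as.integer(f))
      return(NULL)
    }
    regions <- regions_from_labelmap(labels)
    per_marker <- purrr::imap(models, function(model, nm) {
      est <- estimate_cell_levels(model, fr$phase, labels)
      dplyr::mutate(dplyr::inner_join(regions[, c("cell_id", "row", "col",
                                                  "area")],
                                      est, by = "cell_id"),
                    marker = nm, frame = as.integer(f))
    })
    dplyr::bind_rows(per_marker)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out <- out[, c("frame", "cell_id", "row", "col", "area", "marker",
                   "estimate")]
  }
  if (length(failed)) {
    warning("segmentation failed or found no cells in frame(s) ",
            paste(failed, collapse = ", "), call. = FALSE)
  }
  attr(out, "failed_frames") <- failed
  out
}

#' Link per-frame detections into trajectories
#'
#' Greedy nearest-centroid matching between consecutive frames with a
#' maximum displacement gate; unmatched detections start new tracks.
#' Tracks tolerate gaps up to `max_gap` missed frames. When two detections
#' compete for tracks within the gate the pair with the smaller
#' displacement wins and the involved observations are flagged
#' `ambiguous = TRUE`.
#'
#' @param tbl Per-frame table from [run_timelapse()] (or
#'   [timelapse_truth()]).
#' @param gate Maximum centroid displacement per frame, pixels.
#' @param max_gap Maximum number of consecutive missed frames before a
#'   track is closed.
#' @return `tbl` with `track_id` and `ambiguous` columns added (long over
#'   markers; the track assignment is shared across markers of one cell).
#' @export
link_trajectories <- function(tbl, gate = 30, max_gap = 1L) {
  det <- dplyr::distinct(tbl, .data$frame, .data$cell_id, .data$row,
                         .data$col)
  if (nrow(det) == 0L) {
    return(dplyr::mutate(tbl, track_id = integer(0), ambiguous = logical(0)))
  }
  frames_seq <- sort(unique(det$frame))
  det$track_id <- NA_integer_
  det$ambiguous <- FALSE
  next_track <- 1L
  # active tracks: last known position and frame
  active <- tibble::tibble(track_id = integer(), row = numeric(),
                           col = numeric(), last_frame = integer())
  for (f in frames_seq) {
    cur <- which(det$frame == f)
    active <- active[f - active$last_frame <= max_gap + 1L, ]
    if (nrow(active) && length(cur)) {
      d <- outer(active$row, det$row[cur], "-")^2 +
        outer(active$col, det$col[cur], "-")^2
      d <- sqrt(d)
      cand <- which(d <= gate, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(d[cand])
        cand <- cand[ord, , drop = FALSE]
        used_t <- logical(nrow(active))
        used_d <- logical(length(cur))
        # competition: a detection (or track) appearing in >1 candidate pair
        comp_d <- tabulate(cand[, 2], length(cur)) > 1L
        comp_t <- tabulate(cand[, 1], nrow(active)) > 1L
        for (k in seq_len(nrow(cand))) {
          ti <- cand[k, 1]; di <- cand[k, 2]
          if (used_t[ti] || used_d[di]) next
          used_t[ti] <- TRUE
          used_d[di] <- TRUE
          row_i <- cur[di]
          det$track_id[row_i] <- active$track_id[ti]
          det$ambiguous[row_i] <- comp_d[di] || comp_t[ti]
          active$row[ti] <- det$row[row_i]
          active$col[ti] <- det$col[row_i]
          active$last_frame[ti] <- f
        }
      }
    }
    new_idx <- cur[is.na(det$track_id[cur])]
    for (row_i in new_idx) {
      det$track_id[row_i] <- next_track
      active <- dplyr::bind_rows(active,
        tibble::tibble(track_id = next_track, row = det$row[row_i],
                       col = det$col[row_i], last_frame = f))
      next_track <- next_track + 1L
    }
  }
  dplyr::inner_join(tbl, det, by = c("frame", "cell_id", "row", "col"))
}

#' Density-expression analysis of a time-lapse
#'
#' Summarizes each frame (cell count, mean local density from the shared
#' 96 px centroid-disc measure, mean estimated marker level) and
#' correlates mean local density against the mean level across frames.
#'
#' @param tbl Per-frame table from [run_timelapse()] or
#'   [timelapse_truth()].
#' @param marker Marker name to analyze.
#' @param density_radius Disc radius for [local_density()], pixels.
#' @return A `density_report`: `per_frame` tibble and a
#'   `correlation_result` (`result`), plus the marker name.
#' @export
density_analysis <- function(tbl, marker, density_radius = 96) {
  sub <- tbl[tbl$marker == marker, ]
  if (nrow(sub) == 0L) stop("no rows for marker '", marker, "'",
                            call. = FALSE)
  per_frame <- sub |>
    dplyr::group_by(.data$frame) |>
    dplyr::group_modify(function(df, key) {
      tibble::tibble(n_cells = nrow(df),
                     mean_density = mean(local_density(df, density_radius)),
                     mean_level = mean(df$estimate))
    }) |>
    dplyr::ungroup()
  if (nrow(per_frame) < 3L) {
    stop("density analysis needs >= 3 frames", call. = FALSE)
  }
  res <- pearson(per_frame$mean_density, per_frame$mean_level, marker)
  structure(list(per_frame = per_frame, result = res, marker = marker),
            class = "density_report")
}

#' @export
print.density_report <- function(x, ...) {
  cat("<density_report> marker '", x$marker, "', ", nrow(x$per_frame),
      " frames: ", sprintf("r = %.3f, p = %.3g", x$result$r, x$result$p),
      if (x$result$p >= 0.05) " (not significant)", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.density_report <- function(x, ...) x$per_frame

#' @export
glance.density_report <- function(x, ...) tidy(x$result)

#' @rdname density_analysis
#' @param object A `density_report`.
#' @param ... Unused.
#' @export
autoplot.density_report <- function(object, ...) {
  ggplot2::ggplot(object$per_frame,
                  ggplot2::aes(.data$mean_density, .data$mean_level)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$frame)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "mean local density (cells / px^2)",
                  y = paste("mean estimated", object$marker),
                  title = sprintf("r = %.3f, p = %.3g", object$result$r,
                                  object$result$p))
}

#' Marker response of tracked cells to discrete events
#'
#' For each event (a damage/rupture affecting one track at one frame), the
#' marker level averaged over the pre-window `[frame - window, frame - 1]`
#' is compared with the maximum over `[frame, frame + window]`; the
#' response ratio is `max_post / mean_pre`. Windows extending beyond the
#' trajectory are truncated and flagged.
#'
#' @param trajectories Output of [link_trajectories()].
#' @param events Data frame with `track_id` and `frame`.
#' @param marker Marker name.
#' @param window Window half-width in frames.
#' @return Tibble with one row per event: `track_id`, `frame`,
#'   `pre_mean`, `post_max`, `response_ratio`, `truncated`.
#' @export
event_response <- function(trajectories, events, marker, window = 3L) {
  sub <- trajectories[trajectories$marker == marker, ]
  events <- tibble::as_tibble(events)
  stopifnot(all(c("track_id", "frame") %in% names(events)))
  unknown <- setdiff(events$track_id, sub$track_id)
  if (length(unknown)) {
    stop("event references unknown track id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  purrr::pmap_dfr(events[, c("track_id", "frame")], function(track_id, frame) {
    tr <- sub[sub$track_id == track_id, ]
    pre <- tr$estimate[tr$frame >= frame - window & tr$frame < frame]
    post <- tr$estimate[tr$frame >= frame & tr$frame <= frame + window]
    truncated <- frame - window < min(tr$frame) ||
      frame + window > max(tr$frame)
    if (!length(pre) || !length(post)) {
      return(tibble::tibble(track_id = track_id, frame = frame,
                            pre_mean = NA_real_, post_max = NA_real_,
                            response_ratio = NA_real_, truncated = TRUE))
    }
    pre_mean <- mean(pre)
    post_max <- max(post)
    tibble::tibble(track_id = track_id, frame = frame, pre_mean = pre_mean,
                   post_max = post_max,
                   response_ratio = post_max / pre_mean,
                   truncated = truncated)
  })
}
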