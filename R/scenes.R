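#' Specify a synthetic acquisition scene
#'
#' A `scene_spec` describes one simulated field of adherent, flat,
#' roughly-convex cells on a dark background, imaged in a phase-contrast-like
#' channel, a membrane-fluorescence channel (for segmentation), an optional
#' nucleus channel, and one marker-fluorescence channel per
#' [marker_link()]. Ground-truth per-cell marker levels are a stated
#' function of visible morphology, so downstream recovery is testable.
#'
#' All intensities are floating point in `[0, 1]`; images are quantized to
#' 16 bit only on export. Identical specs (including `seed`) regenerate
#' bit-identical frames.
#'
#' @param width,height Field size in pixels (each >= 256 so at least one
#'   training crop fits).
#' @param n_cells Number of cells to place (disjoint footprints; an error is
#'   raised if they cannot be packed).
#' @param cell_radius_mean,cell_radius_sd Mean/SD of the equivalent cell
#'   radius in pixels.
#' @param elongation_range Length-2 range of the cell aspect ratio (>= 1).
#' @param texture_amplitude Peak intra-cell phase texture contrast as an
#'   intensity fraction in `[0, 1]`. Each cell additionally carries its own
#'   texture scale in `[0.3, 1]`, which is the "texture" morphology feature.
#' @param marker_links List of [marker_link()] objects, one per marker
#'   channel.
#' @param noise_sd Additive Gaussian pixel noise SD (intensity units,
#'   clipped at 0).
#' @param background_level Background intensity of all channels.
#' @param seed Integer seed; the sole source of randomness.
#' @return A `scene_spec` object.
#' @seealso [generate_frame()], [timelapse_spec()]
#' @export
scene_spec <- function(width = 512L, height = 512L, n_cells = 25L,
                       cell_radius_mean = 28, cell_radius_sd = 5,
                       elongation_range = c(1, 1.8),
                       texture_amplitude = 0.35,
                       marker_links = list(marker_link()),
                       noise_sd = 0.01, background_level = 0.08,
                       seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_cells = as.integer(n_cells),
               cell_radius_mean = cell_radius_mean,
               cell_radius_sd = cell_radius_sd,
               elongation_range = elongation_range,
               texture_amplitude = texture_amplitude,
               marker_links = marker_links,
               noise_sd = noise_sd,
               background_level = background_level,
               seed = as.integer(seed))
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  if (spec$width < 256L || spec$height < 256L) {
    stop("scene must be at least 256x256 to admit a training crop",
         call. = FALSE)
  }
  if (spec$n_cells < 0L) stop("n_cells must be >= 0", call. = FALSE)
  if (length(spec$elongation_range) != 2L || any(spec$elongation_range < 1)) {
    stop("elongation_range must be two aspect ratios >= 1", call. = FALSE)
  }
  if (spec$texture_amplitude < 0 || spec$texture_amplitude > 1) {
    stop("texture_amplitude must lie in [0, 1]", call. = FALSE)
  }
  if (spec$noise_sd < 0 || spec$background_level < 0) {
    stop("noise_sd and background_level must be >= 0", call. = FALSE)
  }
  nm <- vapply(spec$marker_links, function(l) l$marker_name, character(1))
  if (anyDuplicated(nm)) stop("duplicate marker names", call. = FALSE)
  invisible(spec)
}

#' Link a marker's ground-truth level to cell morphology
#'
#' The ground-truth per-cell level of a marker is
#' `intercept + sum(weights * features) + noise`, clipped at 0. Features
#' are: `area` (pixels / (pi * cell_radius_mean^2), so ~1 for an average
#' cell), `elongation` (aspect ratio), `texture` (the cell's texture scale
#' in `[0.3, 1]`), and `density` (cell centroids within a 96 px disc of the
#' centroid, self included, divided by the disc area in px^2 — note the
#' small magnitude, ~1e-4, so density weights are numerically large).
#'
#' `dynamics` programs the time-lapse behaviour: `"density_up"` /
#' `"density_down"` force a positive / negative density weight of magnitude
#' `density_gain` so the level is monotone in local density by construction;
#' `"damage_transient"` adds `spike * 2^(-(t - t_event)/half_life)` after
#' each damage event affecting the cell; `"static"` applies the link only.
#'
#' @param marker_name Channel name.
#' @param weights Named numeric weights over
#'   `c(area, elongation, texture, density)`; missing names default to 0.
#' @param intercept Baseline intensity.
#' @param noise_sd SD of per-cell, per-frame Gaussian link noise (this is
#'   biological scatter on the level itself, distinct from the scene's
#'   pixel noise).
#' @param dynamics One of `"static"`, `"density_up"`, `"density_down"`,
#'   `"damage_transient"`.
#' @param density_gain Magnitude of the density weight imposed by the
#'   density dynamics (intensity per (cells/px^2)).
#' @param half_life Decay half-life of the damage transient, in frames
#'   (must be > 0 for `damage_transient`).
#' @param spike Amplitude of the damage transient (intensity units).
#' @return A `marker_link` object.
#' @export
marker_link <- function(marker_name = "marker1",
                        weights = c(area = 0.15, elongation = 0,
                                    texture = 0.5, density = 0),
                        intercept = 0.15, noise_sd = 0,
                        dynamics = c("static", "density_up", "density_down",
                                     "damage_transient"),
                        density_gain = 2000, half_life = 3, spike = 0.5) {
  dynamics <- match.arg(dynamics)
  w <- c(area = 0, elongation = 0, texture = 0, density = 0)
  if (length(weights)) {
    bad <- setdiff(names(weights), names(w))
    if (length(bad)) stop("unknown feature weight(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    w[names(weights)] <- weights
  }
  if (dynamics == "density_up") w["density"] <- abs(density_gain)
  if (dynamics == "density_down") w["density"] <- -abs(density_gain)
  if (dynamics == "damage_transient" && half_life <= 0) {
    stop("damage_transient requires half_life > 0 frames", call. = FALSE)
  }
  structure(list(marker_name = marker_name, weights = w,
                 intercept = intercept, noise_sd = noise_sd,
                 dynamics = dynamics, half_life = half_life, spike = spike),
            class = "marker_link")
}

#' Local cell density around each centroid
#'
#' Number of cell centroids (self included) within `radius` pixels of each
#' cell's centroid, divided by the disc area. This is the density feature
#' used both by the simulator's morphology-marker links and by the
#' time-lapse density analysis, so the two agree by construction.
#'
#' @param centroids Data frame with `row`, `col` centroid columns (pixels).
#' @param radius Disc radius in pixels (default 96).
#' @return Numeric vector, cells per px^2.
#' @export
local_density <- function(centroids, radius = 96) {
  n <- nrow(centroids)
  if (n == 0L) return(numeric(0))
  d <- as.matrix(stats::dist(cbind(centroids$row, centroids$col)))
  counts <- rowSums(d <= radius)  # diagonal is 0 <= radius: self included
  counts / (pi * radius^2)
}

# --- internal cell sampling and rasterization --------------------------------

# Sample one cell's shape template: pixel offsets relative to its (integer)
# center, from a randomly oriented ellipse with low-order harmonic wobble.
sample_cell_shape <- function(spec) {
  r <- max(6, rnorm(1, spec$cell_radius_mean, spec$cell_radius_sd))
  q <- runif(1, spec$elongation_range[1], spec$elongation_range[2])
  phi <- runif(1, 0, pi)
  ck <- rnorm(3, 0, 0.04)
  psi <- runif(3, 0, 2 * pi)
  a <- r * sqrt(q)
  b <- r / sqrt(q)
  ext <- ceiling(max(a, b) * 1.2) + 1L
  dj <- rep(-ext:ext, each = 2L * ext + 1L)
  di <- rep(-ext:ext, times = 2L * ext + 1L)
  u <- dj * cos(phi) + di * sin(phi)
  v <- -dj * sin(phi) + di * cos(phi)
  s <- sqrt((u / a)^2 + (v / b)^2)
  th <- atan2(v, u)
  wob <- 1 + ck[1] * cos(2 * th + psi[1]) + ck[2] * cos(3 * th + psi[2]) +
    ck[3] * cos(4 * th + psi[3])
  inside <- s <= pmax(wob, 0.5)
  list(offsets = cbind(di = di[inside], dj = dj[inside]),
       radius = r, elongation = q,
       texture = runif(1, 0.3, 1),
       extent = ext)
}

# Try to place `shape` so that its footprint dilated by 1 px (which keeps
# distinct cells 8-disconnected) misses the committed footprints in `occ`.
# `occ` holds undilated footprints. Returns center/indices or NULL.
try_place <- function(occ, shape, spec, n_attempts = 200L) {
  H <- spec$height; W <- spec$width
  m <- shape$extent + 2L
  if (2L * m + 2L >= min(H, W)) return(NULL)
  for (k in seq_len(n_attempts)) {
    ci <- sample.int(H - 2L * m, 1L) + m
    cj <- sample.int(W - 2L * m, 1L) + m
    idx <- cbind(shape$offsets[, 1] + ci, shape$offsets[, 2] + cj)
    dil <- dilate_indices(idx, H, W)
    if (!any(occ[dil])) return(list(center = c(ci, cj), idx = idx))
  }
  NULL
}

dilate_indices <- function(idx, H, W) {
  di <- rep(-1:1, times = 3L)
  dj <- rep(-1:1, each = 3L)
  i <- pmin(pmax(rep(idx[, 1], times = 9L) + rep(di, each = nrow(idx)), 1L), H)
  j <- pmin(pmax(rep(idx[, 2], times = 9L) + rep(dj, each = nrow(idx)), 1L), W)
  cbind(i, j)
}

# Sample and place n_cells disjoint cells; returns the population state.
sample_population <- function(spec) {
  occ <- matrix(FALSE, spec$height, spec$width)
  cells <- vector("list", spec$n_cells)
  for (id in seq_len(spec$n_cells)) {
    placed <- NULL
    for (retry in 1:20) {
      shape <- sample_cell_shape(spec)
      placed <- try_place(occ, shape, spec)
      if (!is.null(placed)) break
    }
    if (is.null(placed)) {
      stop("impossible packing: could not place ", spec$n_cells,
           " disjoint cells of mean radius ", spec$cell_radius_mean,
           " in a ", spec$height, "x", spec$width, " field", call. = FALSE)
    }
    occ[placed$idx] <- TRUE
    cells[[id]] <- c(shape, list(id = id, center = placed$center))
  }
  cells
}

population_labels <- function(cells, H, W) {
  lab <- matrix(0L, H, W)
  for (cell in cells) {
    idx <- cbind(cell$offsets[, 1] + cell$center[1],
                 cell$offsets[, 2] + cell$center[2])
    lab[idx] <- cell$id
  }
  lab
}

# Per-cell morphology feature table (centroids 0-based).
population_features <- function(cells, labels, spec) {
  if (length(cells) == 0L) {
    return(tibble::tibble(cell_id = integer(), area = integer(),
                          row = numeric(), col = numeric(),
                          elongation = numeric(), texture = numeric(),
                          density = numeric()))
  }
  tab <- purrr::map_dfr(cells, function(cell) {
    i <- cell$offsets[, 1] + cell$center[1]
    j <- cell$offsets[, 2] + cell$center[2]
    tibble::tibble(cell_id = cell$id, area = length(i),
                   row = mean(i) - 1, col = mean(j) - 1,
                   elongation = cell$elongation, texture = cell$texture)
  })
  tab$density <- local_density(tab)
  tab
}

# Ground-truth level of one marker for every cell (single frame, no dynamics).
link_levels <- function(link, feats, spec) {
  if (nrow(feats) == 0L) return(numeric(0))
  f <- cbind(area = feats$area / (pi * spec$cell_radius_mean^2),
             elongation = feats$elongation,
             texture = feats$texture,
             density = feats$density)
  lv <- link$intercept + drop(f %*% link$weights[colnames(f)])
  if (link$noise_sd > 0) lv <- lv + rnorm(length(lv), 0, link$noise_sd)
  unname(pmax(lv, 0))
}

# Smooth zero-mean unit-sd noise field (Perlin-style) for phase texture.
texture_field <- function(H, W, sigma = 2.5) {
  f <- EBImage::gblur(matrix(rnorm(H * W), H, W), sigma = sigma)
  f <- as.matrix(f)
  f / max(sd(f), 1e-12)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

add_pixel_noise <- function(img, sd) {
  if (sd <= 0) return(img)
  pmax(img + matrix(rnorm(length(img), 0, sd), nrow(img), ncol(img)), 0)
}

# Render all channels for a fixed population at given truth levels.
# `levels` is a tibble (cell_id, marker, level).
render_frame <- function(cells, labels, feats, levels, spec) {
  H <- spec$height; W <- spec$width
  bg <- spec$background_level
  membrane_level <- max(0.5, 4 * bg)

  phase <- matrix(bg, H, W)
  membrane <- matrix(bg, H, W)
  nucleus <- matrix(bg, H, W)
  tex <- if (spec$texture_amplitude > 0) texture_field(H, W) else NULL

  for (cell in cells) {
    i <- cell$offsets[, 1] + cell$center[1]
    j <- cell$offsets[, 2] + cell$center[2]
    idx <- cbind(i, j)
    interior <- bg + 0.10
    if (!is.null(tex)) {
      interior <- interior +
        cell$texture * spec$texture_amplitude * tex[idx]
    }
    phase[idx] <- interior
    # bright halo on the footprint rim (pixels with a non-cell 4-neighbour)
    rim <- rim_indices(cell, H, W)
    phase[rim] <- bg + 0.45
    membrane[idx] <- membrane_level
    nr <- max(2, round(cell$radius / 3))
    nuc <- cell$offsets[, 1]^2 + cell$offsets[, 2]^2 <= nr^2
    if (any(nuc)) nucleus[idx[nuc, , drop = FALSE]] <- 0.7
  }

  markers <- list()
  for (link in spec$marker_links) {
    img <- matrix(bg, H, W)
    lv <- levels[levels$marker == link$marker_name, ]
    lvmap <- stats::setNames(lv$level, lv$cell_id)
    for (cell in cells) {
      idx <- cbind(cell$offsets[, 1] + cell$center[1],
                   cell$offsets[, 2] + cell$center[2])
      img[idx] <- lvmap[[as.character(cell$id)]]
    }
    # clipped at 0 only (inside add_pixel_noise): truth levels may exceed 1;
    # quantization to [0, 1] happens at export time
    markers[[link$marker_name]] <- add_pixel_noise(img, spec$noise_sd)
  }

  list(phase = clip01(add_pixel_noise(phase, spec$noise_sd)),
       membrane = clip01(add_pixel_noise(membrane, spec$noise_sd)),
       nucleus = clip01(add_pixel_noise(nucleus, spec$noise_sd)),
       markers = markers)
}

rim_indices <- function(cell, H, W) {
  off <- cell$offsets
  key <- off[, 1] * 100000L + off[, 2]
  nb <- matrix(c(-1L, 0L, 1L, 0L, 0L, -1L, 0L, 1L), ncol = 2, byrow = TRUE)
  interior <- rep(TRUE, nrow(off))
  for (k in 1:4) {
    interior <- interior &
      ((off[, 1] + nb[k, 1]) * 100000L + (off[, 2] + nb[k, 2])) %in% key
  }
  rim <- off[!interior, , drop = FALSE]
  cbind(rim[, 1] + cell$center[1], rim[, 2] + cell$center[2])
}

new_scene_frame <- function(channels, labels, feats, levels, spec) {
  structure(list(phase = channels$phase, membrane = channels$membrane,
                 nucleus = channels$nucleus, markers = channels$markers,
                 truth_labels = as_label_map(labels),
                 truth_levels = levels, truth_cells = feats, spec = spec),
            class = "scene_frame")
}

#' Generate one synthetic scene frame
#'
#' Deterministically renders the scene described by a [scene_spec()]:
#' phase-contrast-like channel (textured cell interiors with a bright edge
#' halo), membrane channel (>= 4x background exactly on cell footprints),
#' nucleus channel, and one marker channel per link, whose per-cell mean
#' equals the ground-truth level up to pixel noise.
#'
#' @param spec A [scene_spec()].
#' @return A `scene_frame`: images plus `truth_labels` ([label_map]),
#'   `truth_levels` (tibble `cell_id`, `marker`, `level`) and `truth_cells`
#'   (tibble of per-cell morphology features).
#' @export
generate_frame <- function(spec) {
  validate_scene_spec(spec)
  withr::with_seed(spec$seed, {
    cells <- sample_population(spec)
    labels <- population_labels(cells, spec$height, spec$width)
    feats <- population_features(cells, labels, spec)
    levels <- purrr::map_dfr(spec$marker_links, function(link) {
      tibble::tibble(cell_id = feats$cell_id, marker = link$marker_name,
                     level = link_levels(link, feats, spec))
    })
    if (nrow(levels) == 0L) {
      levels <- tibble::tibble(cell_id = integer(), marker = character(),
                               level = numeric())
    }
    channels <- render_frame(cells, labels, feats, levels, spec)
    new_scene_frame(channels, labels, feats, levels, spec)
  })
}

#' Specify a synthetic time-lapse sequence
#'
#' @param base A [scene_spec()] describing the initial frame.
#' @param n_frames Number of frames (>= 2).
#' @param frame_interval Minutes between frames (metadata; default 30, the
#'   usual live-imaging cadence for adherent cultures).
#' @param motion_sd Per-frame random-walk SD of cell centroids, pixels.
#' @param density_growth Cells added per frame (confluence growth).
#' @param rupture_events Data frame with `cell_id`, `frame`: damage events.
#'   A `damage_transient` marker spikes at the event frame and decays with
#'   its half-life; the cell is removed from the scene `rupture_lag` frames
#'   after the event.
#' @param rupture_lag Frames a damaged cell persists (showing the decaying
#'   transient) before removal; 0 removes it immediately after its event
#'   frame.
#' @return A `timelapse_spec` object.
#' @export
timelapse_spec <- function(base = scene_spec(), n_frames = 10L,
                           frame_interval = 30, motion_sd = 2,
                           density_growth = 0L,
                           rupture_events = NULL, rupture_lag = 0L) {
  if (n_frames < 2L) stop("a time-lapse needs n_frames >= 2", call. = FALSE)
  if (is.null(rupture_events)) {
    rupture_events <- tibble::tibble(cell_id = integer(), frame = integer())
  }
  rupture_events <- tibble::as_tibble(rupture_events)
  stopifnot(all(c("cell_id", "frame") %in% names(rupture_events)))
  structure(list(base = base, n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, motion_sd = motion_sd,
                 density_growth = as.integer(density_growth),
                 rupture_events = rupture_events,
                 rupture_lag = as.integer(rupture_lag)),
            class = "timelapse_spec")
}

#' Generate a synthetic time-lapse sequence
#'
#' Cell centroids follow seeded random walks (collisions resolved by
#' holding position), new cells appear at `density_growth` per frame, and
#' programmed marker dynamics respond to local density and damage events.
#' Ruptured cells disappear `rupture_lag` frames after their event.
#'
#' @param tspec A [timelapse_spec()].
#' @return A `timelapse` object: `frames` (list of `scene_frame`),
#'   `events` (tibble), `tspec`.
#' @export
generate_timelapse <- function(tspec) {
  spec <- tspec$base
  validate_scene_spec(spec)
  ev <- tspec$rupture_events
  withr::with_seed(spec$seed, {
    cells <- sample_population(spec)
    if (nrow(ev) && !all(ev$cell_id %in% vapply(cells, `[[`, 0L, "id"))) {
      stop("rupture event names a nonexistent cell id", call. = FALSE)
    }
    next_id <- length(cells) + 1L
    frames <- vector("list", tspec$n_frames)
    for (f in seq_len(tspec$n_frames)) {
      if (f > 1L) {
        cells <- move_population(cells, tspec, spec)
        if (tspec$density_growth > 0L) {
          occ <- footprint_occupancy(cells, spec)
          for (k in seq_len(tspec$density_growth)) {
            shape <- sample_cell_shape(spec)
            placed <- try_place(occ, shape, spec)
            if (is.null(placed)) next  # field full: growth saturates
            occ[placed$idx] <- TRUE
            cells <- c(cells, list(c(shape, list(id = next_id,
                                                 center = placed$center))))
            next_id <- next_id + 1L
          }
        }
        gone <- ev$cell_id[ev$frame + tspec$rupture_lag < f]
        if (length(gone)) {
          cells <- cells[!vapply(cells, `[[`, 0L, "id") %in% gone]
        }
      }
      labels <- population_labels(cells, spec$height, spec$width)
      feats <- population_features(cells, labels, spec)
      levels <- purrr::map_dfr(spec$marker_links, function(link) {
        lv <- link_levels(link, feats, spec)
        if (link$dynamics == "damage_transient" && nrow(ev)) {
          for (e in seq_len(nrow(ev))) {
            hit <- feats$cell_id == ev$cell_id[e] & f >= ev$frame[e]
            lv[hit] <- lv[hit] +
              link$spike * 2^(-(f - ev$frame[e]) / link$half_life)
          }
        }
        tibble::tibble(cell_id = feats$cell_id, marker = link$marker_name,
                       level = pmax(lv, 0))
      })
      channels <- render_frame(cells, labels, feats, levels, spec)
      frames[[f]] <- new_scene_frame(channels, labels, feats, levels, spec)
    }
    structure(list(frames = frames, events = ev, tspec = tspec),
              class = "timelapse")
  })
}

# Occupancy of committed (undilated) footprints; candidates are checked
# with a 1 px dilation so distinct cells stay 8-disconnected.
footprint_occupancy <- function(cells, spec) {
  occ <- matrix(FALSE, spec$height, spec$width)
  for (cell in cells) {
    occ[cbind(cell$offsets[, 1] + cell$center[1],
              cell$offsets[, 2] + cell$center[2])] <- TRUE
  }
  occ
}

# Random-walk step for every cell. Cells are processed in id order against
# an occupancy holding already-moved cells at their new positions and the
# rest at their previous ones; a cell whose proposed step collides keeps
# its previous position, which is always available because footprints are
# strictly disjoint.
move_population <- function(cells, tspec, spec) {
  H <- spec$height; W <- spec$width
  occ <- footprint_occupancy(cells, spec)
  out <- vector("list", length(cells))
  for (k in seq_along(cells)) {
    cell <- cells[[k]]
    prev_idx <- cbind(cell$offsets[, 1] + cell$center[1],
                      cell$offsets[, 2] + cell$center[2])
    occ[prev_idx] <- FALSE
    m <- cell$extent + 2L
    step <- round(rnorm(2, 0, tspec$motion_sd))
    ctr <- c(pmin(pmax(cell$center[1] + step[1], m + 1L), H - m),
             pmin(pmax(cell$center[2] + step[2], m + 1L), W - m))
    idx <- cbind(cell$offsets[, 1] + ctr[1], cell$offsets[, 2] + ctr[2])
    if (any(occ[dilate_indices(idx, H, W)])) {
      ctr <- cell$center
      idx <- prev_idx
    }
    occ[idx] <- TRUE
    cell$center <- ctr
    out[[k]] <- cell
  }
  out
}

#' Ground-truth per-cell table of a time-lapse
#'
#' Flattens a generated [generate_timelapse()] object into the per-frame,
#' per-cell, per-marker long table the time-lapse analyses consume, using
#' the generator's own truth levels as the `estimate` column. This is the
#' network-free route for validating the density and event-response
#' analyses in isolation.
#'
#' @param tl A `timelapse` object.
#' @return Tibble with `frame`, `cell_id`, `row`, `col`, `area`, `marker`,
#'   `estimate`.
#' @export
timelapse_truth <- function(tl) {
  stopifnot(inherits(tl, "timelapse"))
  purrr::imap_dfr(tl$frames, function(fr, f) {
    dplyr::inner_join(
      dplyr::mutate(fr$truth_cells, frame = as.integer(f)),
      dplyr::rename(fr$truth_levels, estimate = "level"),
      by = "cell_id"
    )[, c("frame", "cell_id", "row", "col", "area", "marker", "estimate")]
  })
}

#' Write a scene frame to disk
#'
#' One 16-bit grayscale TIFF per channel plus a JSON sidecar holding the
#' run-length-encoded truth labels, truth levels and morphology table.
#'
#' @param frame A `scene_frame`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default `"frame"`).
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(frame, dir, prefix = "frame") {
  stopifnot(inherits(frame, "scene_frame"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  chans <- c(list(phase = frame$phase, membrane = frame$membrane,
                  nucleus = frame$nucleus), frame$markers)
  for (nm in names(chans)) {
    p <- file.path(dir, paste0(prefix, "_", nm, ".tif"))
    write_image(chans[[nm]], p)
    paths <- c(paths, p)
  }
  sidecar <- list(truth_labels = rle_encode(label_matrix(frame$truth_labels)),
                  truth_levels = frame$truth_levels,
                  truth_cells = frame$truth_cells)
  p <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(sidecar, p, digits = NA, dataframe = "columns")
  invisible(c(paths, p))
}

#' Read a scene frame written by [write_scene()]
#'
#' @param dir Directory containing the channel TIFFs and truth sidecar.
#' @param prefix File name prefix used at write time.
#' @return A `scene_frame` (with `spec = NULL`; intensities quantized to
#'   16 bit by the round trip).
#' @export
read_scene <- function(dir, prefix = "frame") {
  files <- list.files(dir, pattern = paste0("^", prefix, "_.*\\.tif$"),
                      full.names = TRUE)
  if (!length(files)) stop("no channels found under ", dir, call. = FALSE)
  nms <- sub(paste0("^", prefix, "_(.*)\\.tif$"), "\\1", basename(files))
  chans <- stats::setNames(lapply(files, read_image), nms)
  truth <- jsonlite::read_json(file.path(dir, paste0(prefix, "_truth.json")),
                               simplifyVector = TRUE)
  core <- c("phase", "membrane", "nucleus")
  structure(list(phase = chans$phase, membrane = chans$membrane,
                 nucleus = chans$nucleus,
                 markers = chans[setdiff(nms, core)],
                 truth_labels = as_label_map(rle_decode(truth$truth_labels)),
                 truth_levels = tibble::as_tibble(truth$truth_levels),
                 truth_cells = tibble::as_tibble(truth$truth_cells),
                 spec = NULL),
            class = "scene_frame")
}

#' @export
print.scene_frame <- function(x, ...) {
  cat("<scene_frame> ", nrow(x$phase), "x", ncol(x$phase), " px, ",
      n_regions(x$truth_labels), " cells, markers: ",
      paste(names(x$markers), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Plot the channels of a scene frame
#'
#' @param frame A `scene_frame`.
#' @param channels Channel names to show (default all).
#' @return A ggplot object (rasters faceted by channel).
#' @export
plot_scene <- function(frame, channels = NULL) {
  chans <- c(list(phase = frame$phase, membrane = frame$membrane,
                  nucleus = frame$nucleus), frame$markers)
  if (!is.null(channels)) chans <- chans[channels]
  df <- purrr::imap_dfr(chans, function(img, nm) {
    tibble::tibble(channel = nm,
                   row = rep(seq_len(nrow(img)) - 1L, times = ncol(img)),
                   col = rep(seq_len(ncol(img)) - 1L, each = nrow(img)),
                   intensity = as.vector(img))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity")
}
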