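#' Label map: one integer id per cell footprint
#'
#' Wraps an integer matrix whose values are exactly `{0, 1, ..., n_regions}`
#' with 0 = background. All per-cell accounting in the package runs over a
#' `label_map`. Coordinates throughout are 0-based, row-major, with
#' half-open bounding boxes.
#'
#' @param labels Integer matrix of region ids (0 = background).
#' @return A `label_map` object.
#' @export
as_label_map <- function(labels) {
  if (inherits(labels, "label_map")) return(labels)
  stopifnot(is.matrix(labels))
  m <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  ids <- sort(unique(m[m > 0L]))
  n <- length(ids)
  if (n > 0L && !identical(ids, seq_len(n))) {
    # compact nonconsecutive ids to 1..n
    m[m > 0L] <- match(m[m > 0L], ids)
  }
  structure(list(labels = m, n_regions = n), class = "label_map")
}

label_matrix <- function(x) {
  if (inherits(x, "label_map")) x$labels else x
}

#' Number of regions in a label map
#' @param x A [label_map][as_label_map].
#' @return Integer count.
#' @export
n_regions <- function(x) {
  stopifnot(inherits(x, "label_map"))
  x$n_regions
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map> ", nrow(x$labels), "x", ncol(x$labels), " px, ",
      x$n_regions, " regions\n", sep = "")
  invisible(x)
}

#' Segmentation configuration
#'
#' Parameters for extracting cell regions from a membrane-fluorescence
#' image. Defaults: Otsu threshold (parameter-free and reproducible),
#' 8-connectivity, hole filling, a 1 px morphological opening to suppress
#' speckle, minimum region area 100 px, and exclusion of border-touching
#' regions (partial cells bias per-cell means).
#'
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Intensity threshold in `[0, 1]`, used iff
#'   `threshold_method = "fixed"`.
#' @param min_area Smallest accepted region, pixels (>= 1).
#' @param connectivity 4 or 8 (pixel adjacency).
#' @param fill_holes Fill enclosed background holes before filtering?
#' @param border_policy `"exclude"` drops regions touching the image
#'   border; `"keep"` retains them.
#' @param opening_radius Radius of the binary opening applied to the mask
#'   (0 disables).
#' @return A `segmentation_config` object.
#' @export
segmentation_config <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = 0.5,
                                min_area = 100L,
                                connectivity = 8L,
                                fill_holes = TRUE,
                                border_policy = c("exclude", "keep"),
                                opening_radius = 1L) {
  threshold_method <- match.arg(threshold_method)
  border_policy <- match.arg(border_policy)
  if (min_area < 1L) stop("min_area must be >= 1", call. = FALSE)
  if (opening_radius < 0L) stop("opening_radius must be >= 0", call. = FALSE)
  if (!connectivity %in% c(4L, 8L)) {
    stop("connectivity must be 4 or 8", call. = FALSE)
  }
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_area = as.integer(min_area),
                 connectivity = as.integer(connectivity),
                 fill_holes = isTRUE(fill_holes),
                 border_policy = border_policy,
                 opening_radius = as.integer(opening_radius)),
            class = "segmentation_config")
}

# Otsu threshold on a [0,1] image: maximize between-class variance over a
# 256-bin histogram. With well-separated modes the criterion is flat
# across the empty gap; the midpoint of the maximal run is taken so the
# threshold sits centrally, not at the gap's edge.
otsu_threshold <- function(image, n_bins = 256L) {
  h <- tabulate(pmin(pmax(floor(image * n_bins), 0), n_bins - 1L) + 1L,
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(n_bins) - 0.5))
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  best <- which(sigma_b >= max(sigma_b) - 1e-9)
  mean(range(best)) / n_bins
}

#' Extract cell regions from a membrane-fluorescence image
#'
#' Binarizes the membrane channel, optionally fills holes and opens the
#' mask, labels connected components under the configured connectivity,
#' removes small and (optionally) border-touching regions, and renumbers
#' the survivors 1..n.
#'
#' A constant image under Otsu yields zero regions with a warning, not an
#' error: an empty field is a legitimate observation.
#'
#' @param membrane Numeric matrix in `[0, 1]`.
#' @param config A [segmentation_config()].
#' @return A [label_map][as_label_map].
#' @export
binarize_and_label <- function(membrane, config = segmentation_config()) {
  stopifnot(is.matrix(membrane), length(membrane) > 0L)
  if (config$threshold_method == "fixed") {
    if (config$fixed_threshold < 0 || config$fixed_threshold > 1) {
      stop("fixed_threshold outside the representable [0, 1] range",
           call. = FALSE)
    }
    thr <- config$fixed_threshold
  } else {
    if (diff(range(membrane)) == 0) {
      warning("constant image: Otsu threshold undefined, returning 0 regions",
              call. = FALSE)
      return(as_label_map(matrix(0L, nrow(membrane), ncol(membrane))))
    }
    thr <- otsu_threshold(membrane)
  }
  mask <- membrane > thr
  if (config$fill_holes && any(mask)) {
    mask <- as.matrix(EBImage::fillHull(mask * 1)) > 0
  }
  if (config$opening_radius > 0L && any(mask)) {
    brush <- EBImage::makeBrush(2L * config$opening_radius + 1L,
                                shape = "disc")
    mask <- as.matrix(EBImage::opening(mask * 1, brush)) > 0
  }
  lab <- cb_label(mask, config$connectivity)
  lab <- filter_regions(lab, config)
  as_label_map(lab)
}

filter_regions <- function(lab, config) {
  n <- max(lab)
  if (n == 0L) return(lab)
  keep <- tabulate(lab[lab > 0L], nbins = n) >= config$min_area
  if (config$border_policy == "exclude") {
    border_ids <- unique(c(lab[1, ], lab[nrow(lab), ],
                           lab[, 1], lab[, ncol(lab)]))
    keep[setdiff(border_ids, 0L)] <- FALSE
  }
  remap <- integer(n)
  remap[keep] <- seq_len(sum(keep))
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

#' Tabulate the regions of a label map
#'
#' @param labels A [label_map][as_label_map] (or integer matrix).
#' @return A tibble with one row per region, sorted by `cell_id`: `area`
#'   (pixels), `row`/`col` (0-based centroid), and the half-open 0-based
#'   bounding box `min_row`, `min_col`, `max_row`, `max_col`.
#' @export
regions_from_labelmap <- function(labels) {
  m <- label_matrix(as_label_map(labels))
  sel <- which(m > 0L)
  if (!length(sel)) {
    return(tibble::tibble(cell_id = integer(), area = integer(),
                          row = numeric(), col = numeric(),
                          min_row = integer(), min_col = integer(),
                          max_row = integer(), max_col = integer()))
  }
  id <- m[sel]
  i0 <- (sel - 1L) %% nrow(m)       # 0-based row
  j0 <- (sel - 1L) %/% nrow(m)      # 0-based col
  df <- tibble::tibble(cell_id = id, i = i0, j = j0)
  out <- df |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(area = dplyr::n(),
                     row = mean(.data$i), col = mean(.data$j),
                     min_row = min(.data$i), min_col = min(.data$j),
                     max_row = max(.data$i) + 1L, max_col = max(.data$j) + 1L,
                     .groups = "drop") |>
    dplyr::arrange(.data$cell_id)
  out$area <- as.integer(out$area)
  out
}

#' Match regions between two segmentations of the same field
#'
#' Pairs regions by maximal pixel overlap (greedy on descending overlap,
#' each id used at most once) and drops pairs with Jaccard index < 0.5.
#' Used to pair cells across two segmentations of one field of view, e.g.
#' before and after fixation.
#'
#' @param a,b [label_map][as_label_map]s of identical dimensions.
#' @param min_jaccard Minimum Jaccard overlap to retain a pair (default
#'   0.5).
#' @return Tibble `id_a`, `id_b`, `overlap` (pixels), `jaccard`.
#' @export
match_regions <- function(a, b, min_jaccard = 0.5) {
  ma <- label_matrix(as_label_map(a))
  mb <- label_matrix(as_label_map(b))
  if (!identical(dim(ma), dim(mb))) {
    stop("label maps have different dimensions", call. = FALSE)
  }
  na <- max(ma); nb <- max(mb)
  empty <- tibble::tibble(id_a = integer(), id_b = integer(),
                          overlap = integer(), jaccard = numeric())
  if (na == 0L || nb == 0L) return(empty)
  sel <- ma > 0L & mb > 0L
  if (!any(sel)) return(empty)
  ov <- table(id_a = ma[sel], id_b = mb[sel])
  area_a <- tabulate(ma[ma > 0L], nbins = na)
  area_b <- tabulate(mb[mb > 0L], nbins = nb)
  cand <- as.data.frame(ov, stringsAsFactors = FALSE)
  cand <- cand[cand$Freq > 0L, ]
  cand$id_a <- as.integer(cand$id_a)
  cand$id_b <- as.integer(cand$id_b)
  cand$jaccard <- cand$Freq /
    (area_a[cand$id_a] + area_b[cand$id_b] - cand$Freq)
  cand <- cand[order(-cand$Freq, cand$id_a, cand$id_b), ]
  used_a <- logical(na); used_b <- logical(nb)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    ia <- cand$id_a[k]; ib <- cand$id_b[k]
    if (!used_a[ia] && !used_b[ib] && cand$jaccard[k] >= min_jaccard) {
      keep[k] <- TRUE
      used_a[ia] <- TRUE
      used_b[ib] <- TRUE
    }
  }
  out <- cand[keep, c("id_a", "id_b", "Freq", "jaccard")]
  names(out)[3] <- "overlap"
  out <- out[order(out$id_a), ]
  tibble::as_tibble(out)
}
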