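#' Per-cell mean intensities of an image
#'
#' The area-normalized per-cell mean: for each region, the sum of the image
#' over the region's pixels divided by the region's area. Background is
#' excluded; means are computed in floating point regardless of input bit
#' depth.
#'
#' @param image Numeric matrix.
#' @param labels A [label_map][as_label_map] of identical dimensions.
#' @return Tibble `cell_id`, `mean`, sorted by `cell_id` (empty for an
#'   empty label map).
#' @export
measure_cell_means <- function(image, labels) {
  labels <- as_label_map(labels)
  m <- label_matrix(labels)
  if (!identical(dim(image), dim(m))) {
    stop("image and label map have different dimensions", call. = FALSE)
  }
  n <- n_regions(labels)
  if (n == 0L) return(tibble::tibble(cell_id = integer(), mean = numeric()))
  sel <- m > 0L
  id <- m[sel]
  sums <- vapply(split(image[sel], id), sum, numeric(1))
  areas <- tabulate(id, nbins = n)
  tibble::tibble(cell_id = seq_len(n), mean = unname(sums) / areas)
}

#' Build a per-cell-average regression target image
#'
#' Replaces every cell region of a marker image by its area-normalized mean
#' intensity and every background pixel by `background_value`. This is the
#' image the encoder-decoder regresses: total fluorescence per region is
#' conserved (`mean * area = region sum`), and applying the operation twice
#' is idempotent.
#'
#' @inheritParams measure_cell_means
#' @param background_value Intensity assigned outside all regions (default
#'   0, an unambiguous non-cell signal).
#' @return A `target_image`: list with `values` (matrix), `source_labels`
#'   (the label map), `background_value`.
#' @export
build_target <- function(image, labels, background_value = 0) {
  labels <- as_label_map(labels)
  m <- label_matrix(labels)
  means <- measure_cell_means(image, labels)
  values <- matrix(background_value, nrow(m), ncol(m))
  if (nrow(means) > 0L) {
    sel <- m > 0L
    values[sel] <- means$mean[m[sel]]
  }
  structure(list(values = values, source_labels = labels,
                 background_value = background_value),
            class = "target_image")
}

#' @export
print.target_image <- function(x, ...) {
  cat("<target_image> ", nrow(x$values), "x", ncol(x$values), " px, ",
      n_regions(x$source_labels), " regions, background ",
      x$background_value, "\n", sep = "")
  invisible(x)
}

#' Pair a phase image with its regression target
#'
#' Bundles an aligned (input, target) image pair for training. Intensity
#' normalization happens inside [train_model()], which records the dataset
#' statistics in the checkpoint so the transform is explicit and
#' reversible.
#'
#' @param phase Phase-contrast matrix.
#' @param target A [build_target()] result (or plain matrix of identical
#'   dimensions).
#' @return A `training_pair`.
#' @export
pair_for_training <- function(phase, target) {
  tval <- if (inherits(target, "target_image")) target$values else target
  labels <- if (inherits(target, "target_image")) target$source_labels
            else NULL
  if (!identical(dim(phase), dim(tval))) {
    stop("phase and target dimensions differ", call. = FALSE)
  }
  structure(list(phase = phase, target = tval, labels = labels),
            class = "training_pair")
}

#' Normalize / denormalize intensities by recorded constants
#'
#' `x_norm = (x - offset) / scale`; the inverse restores the original
#' intensities exactly (up to float round-off).
#'
#' @param x Numeric array.
#' @param norm List with `offset` and `scale`.
#' @return Transformed array.
#' @export
normalize_intensity <- function(x, norm) (x - norm$offset) / norm$scale

#' @rdname normalize_intensity
#' @export
denormalize_intensity <- function(x, norm) x * norm$scale + norm$offset
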