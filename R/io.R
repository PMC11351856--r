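#' Read a grayscale microscopy image
#'
#' Reads an 8- or 16-bit grayscale TIFF or PNG into a floating-point matrix
#' scaled to `[0, 1]`. The original bit depth is recorded in the
#' `"bit_depth"` attribute so round-tripping is explicit.
#'
#' @param path Path to a `.tif`, `.tiff` or `.png` file.
#' @return A numeric matrix in `[0, 1]` with attribute `bit_depth`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop("image file does not exist: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tryCatch(
      tiff::readTIFF(path, info = TRUE),
      error = function(e) stop("failed to read TIFF '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    ),
    png = tryCatch(
      png::readPNG(path, info = TRUE),
      error = function(e) stop("failed to read PNG '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    ),
    stop("unsupported image format '", ext, "' for: ", path, call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) {
      img <- img[, , 1L]
    } else {
      stop("multi-channel (RGB/RGBA) image not supported: ", path,
           call. = FALSE)
    }
  }
  # readTIFF attaches metadata as attributes; readPNG uses an "info" list
  bps <- attr(img, "bits.per.sample", exact = TRUE) %||%
    attr(img, "info", exact = TRUE)$bit.depth
  depth <- if (is.null(bps)) 8L else as.integer(bps[1])
  dm <- dim(img)
  attributes(img) <- list(dim = dm)
  attr(img, "bit_depth") <- depth
  img
}

#' Write a grayscale image
#'
#' Clips to `[0, 1]` and quantizes to the requested bit depth. TIFF or PNG
#' by extension.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param path Output path (`.tif`/`.tiff`/`.png`).
#' @param bits Bits per sample, 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 16L) {
  stopifnot(is.matrix(image), bits %in% c(8L, 16L))
  img <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits)),
    png = png::writePNG(img, path),
    stop("unsupported image format '", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' Write a label map as a 16-bit label TIFF
#'
#' Integer labels are stored in the 16-bit sample values directly
#' (`value = label`), which bounds usable ids at 65535 per field.
#'
#' @param labels A [label_map] object or integer matrix.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_labelmap <- function(labels, path) {
  m <- label_matrix(labels)
  if (max(m) > 65535L) stop("more than 65535 labels cannot be stored", call. = FALSE)
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label map written by [write_labelmap()]
#' @param path Path to a 16-bit label TIFF.
#' @return A [label_map].
#' @export
read_labelmap <- function(path) {
  m <- tiff::readTIFF(path)
  as_label_map(matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)))
}

#' Run-length encode an integer matrix (for JSON sidecars)
#' @param m Integer matrix.
#' @return List with `dim`, `lengths`, `values`.
#' @keywords internal
#' @export
rle_encode <- function(m) {
  r <- rle(as.integer(m))
  list(dim = dim(m), lengths = r$lengths, values = r$values)
}

#' Decode the output of [rle_encode()]
#' @param x List with `dim`, `lengths`, `values`.
#' @return Integer matrix.
#' @keywords internal
#' @export
rle_decode <- function(x) {
  matrix(inverse.rle(structure(list(lengths = as.integer(x$lengths),
                                    values = as.integer(x$values)),
                               class = "rle")),
         nrow = x$dim[1], ncol = x$dim[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
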