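#' Pearson product-moment correlation with two-sided p-value
#'
#' `r = cov(x, y) / (sd(x) * sd(y))`; significance from the exact
#' t-distribution (not a normal approximation, since per-frame cell counts
#' can be small): `t = r * sqrt((n - 2) / (1 - r^2))` against `t_{n-2}`,
#' two-sided. The conventional significance threshold used throughout the
#' package's reports is p < 0.05.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, neither constant.
#' @param marker_name Optional marker label carried in the result.
#' @return A `correlation_result` with fields `r`, `p`, `n`, `marker_name`.
#' @export
pearson <- function(x, y, marker_name = NA_character_) {
  if (length(x) != length(y)) {
    stop("x and y have different lengths", call. = FALSE)
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need n >= 3 observations for a p-value", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * sd(x) * sd(y))
  r <- min(max(r, -1), 1)
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, p = p, n = n, marker_name = marker_name),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result>", if (!is.na(x$marker_name)) x$marker_name else "",
      sprintf(" r = %.3f, p = %.3g, n = %d\n", x$r, x$p, x$n))
  invisible(x)
}

#' @export
tidy.correlation_result <- function(x, ...) {
  tibble::tibble(marker = x$marker_name, r = x$r, p = x$p, n = x$n,
                 significant = x$p < 0.05)
}

#' @export
glance.correlation_result <- function(x, ...) tidy(x)

#' Correlate measured against estimated per-cell levels
#'
#' Joins the two tables on `cell_id` (ids present in only one table are
#' reported and excluded listwise) and computes the Pearson correlation
#' over the intersection.
#'
#' @param measured Tibble `cell_id`, `mean` (or `estimate`) of measured
#'   levels, as from [measure_cell_means()].
#' @param estimated Tibble `cell_id`, `estimate` of model estimates, as
#'   from [estimate_cell_levels()].
#' @param marker_name Optional marker label.
#' @return A `correlation_result`; the joined pairs are attached as
#'   attribute `"pairs"`.
#' @export
evaluate_model <- function(measured, estimated,
                           marker_name = NA_character_) {
  m <- tibble::as_tibble(measured)
  e <- tibble::as_tibble(estimated)
  if ("mean" %in% names(m)) m <- dplyr::rename(m, measured = "mean")
  if ("estimate" %in% names(m)) m <- dplyr::rename(m, measured = "estimate")
  if ("mean" %in% names(e)) e <- dplyr::rename(e, estimate = "mean")
  joined <- dplyr::inner_join(m[, c("cell_id", "measured")],
                              e[, c("cell_id", "estimate")], by = "cell_id")
  dropped <- length(union(m$cell_id, e$cell_id)) - nrow(joined)
  if (nrow(joined) < 3L) {
    stop("fewer than 3 cells shared between measured and estimated sets",
         call. = FALSE)
  }
  if (dropped > 0L) {
    message(dropped, " cell id(s) present in only one set were excluded")
  }
  res <- pearson(joined$measured, joined$estimate, marker_name)
  attr(res, "pairs") <- joined
  res
}

#' Paired-condition comparison of model estimates on one field
#'
#' Segments both frames from their membrane channels, pairs cells across
#' the two segmentations by Jaccard-validated overlap ([match_regions()]),
#' runs the model on both phase images, and correlates the paired per-cell
#' estimates. This mirrors comparing model inference on the same field of
#' view imaged under two conditions (e.g. live vs fixed). The correlation
#' is reported without thresholding; interpretation is left to the caller.
#'
#' @param frame_a,frame_b Lists with at least `phase` and `membrane`
#'   matrices (e.g. `scene_frame`s), identical dimensions.
#' @param model A `trained_model`.
#' @param seg A [segmentation_config()].
#' @param condition_a,condition_b Labels for the two conditions.
#' @return A `paired_comparison`: condition labels, the per-cell pair
#'   table, and the `correlation_result`.
#' @export
compare_conditions <- function(frame_a, frame_b, model,
                               seg = segmentation_config(),
                               condition_a = "a", condition_b = "b") {
  if (!identical(dim(frame_a$phase), dim(frame_b$phase))) {
    stop("frames are not the same field of view (dimensions differ)",
         call. = FALSE)
  }
  lab_a <- binarize_and_label(frame_a$membrane, seg)
  lab_b <- binarize_and_label(frame_b$membrane, seg)
  pairs <- match_regions(lab_a, lab_b)
  if (nrow(pairs) < 3L) {
    stop("fewer than 3 cells matched between the two conditions",
         call. = FALSE)
  }
  est_a <- estimate_cell_levels(model, frame_a$phase, lab_a)
  est_b <- estimate_cell_levels(model, frame_b$phase, lab_b)
  tab <- pairs |>
    dplyr::inner_join(dplyr::rename(est_a, id_a = "cell_id",
                                    estimate_a = "estimate"), by = "id_a") |>
    dplyr::inner_join(dplyr::rename(est_b, id_b = "cell_id",
                                    estimate_b = "estimate"), by = "id_b")
  res <- pearson(tab$estimate_a, tab$estimate_b, model$marker_name)
  structure(list(condition_a = condition_a, condition_b = condition_b,
                 pairs = tab, result = res),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat("<paired_comparison> ", x$condition_a, " vs ", x$condition_b, ": ",
      sprintf("r = %.3f, p = %.3g, n = %d\n", x$result$r, x$result$p,
              x$result$n), sep = "")
  invisible(x)
}

#' @export
tidy.paired_comparison <- function(x, ...) x$pairs

#' @export
glance.paired_comparison <- function(x, ...) {
  dplyr::mutate(tidy(x$result), condition_a = x$condition_a,
                condition_b = x$condition_b)
}

#' @rdname compare_conditions
#' @param object A `paired_comparison`.
#' @param ... Unused.
#' @export
autoplot.paired_comparison <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(.data$estimate_a, .data$estimate_b)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(linetype = "dashed") +
    ggplot2::labs(x = object$condition_a, y = object$condition_b,
                  title = sprintf("r = %.3f (n = %d)", object$result$r,
                                  object$result$n))
}

#' Export a measured-vs-estimated scatter table
#'
#' Writes a CSV with a commented header block (`marker`, `r`, `p`, `n`)
#' followed by one row per cell (`marker`, `cell_id`, `measured`,
#' `estimate`), and optionally a scatter-plot file. Re-reading the CSV and
#' recomputing the correlation reproduces the header values.
#'
#' @param result A `correlation_result` from [evaluate_model()] (must
#'   carry its `"pairs"` attribute).
#' @param path Output `.csv` path.
#' @param plot_path Optional path for a ggplot scatter (`.png`/`.pdf`).
#' @return The scatter tibble, invisibly.
#' @export
export_scatter <- function(result, path, plot_path = NULL) {
  pairs <- attr(result, "pairs")
  if (is.null(pairs)) {
    stop("result carries no per-cell pairs (use evaluate_model())",
         call. = FALSE)
  }
  tab <- tibble::tibble(marker = result$marker_name,
                        cell_id = pairs$cell_id,
                        measured = pairs$measured,
                        estimate = pairs$estimate)
  header <- c(sprintf("# marker: %s", result$marker_name),
              sprintf("# r: %.15g", result$r),
              sprintf("# p: %.15g", result$p),
              sprintf("# n: %d", result$n))
  writeLines(header, path)
  readr::write_csv(tab, path, append = TRUE, col_names = TRUE)
  if (!is.null(plot_path)) {
    g <- plot_scatter(tab)
    ggplot2::ggsave(plot_path, g, width = 5, height = 5)
  }
  invisible(tab)
}

#' Scatter plot of measured vs estimated per-cell levels
#' @param tab Tibble with `measured` and `estimate` columns.
#' @return A ggplot object.
#' @export
plot_scatter <- function(tab) {
  ggplot2::ggplot(tab, ggplot2::aes(.data$measured, .data$estimate)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "measured per-cell mean",
                  y = "estimated per-cell mean")
}
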