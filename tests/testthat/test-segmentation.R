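test_that("an all-zero image yields zero regions with a warning", {
  img <- matrix(0, 32, 32)
  expect_warning(lab <- binarize_and_label(img), "constant image")
  expect_identical(n_regions(lab), 0L)
  expect_identical(nrow(regions_from_labelmap(lab)), 0L)
})

test_that("two bright squares are recovered with exact areas", {
  img <- matrix(0, 64, 64)
  img[5:14, 5:14] <- 1
  img[40:49, 30:39] <- 1
  cfg <- segmentation_config(threshold_method = "fixed",
                             fixed_threshold = 0.5, min_area = 50L,
                             opening_radius = 0L, border_policy = "keep")
  lab <- binarize_and_label(img, cfg)
  expect_identical(n_regions(lab), 2L)
  regions <- regions_from_labelmap(lab)
  expect_identical(regions$area, c(100L, 100L))
})

test_that("border-touching regions are dropped under the exclude policy", {
  img <- matrix(0, 40, 40)
  img[1:12, 5:16] <- 1  # touches the top border
  cfg <- segmentation_config(threshold_method = "fixed",
                             fixed_threshold = 0.5, min_area = 10L,
                             opening_radius = 0L)
  expect_identical(n_regions(binarize_and_label(img, cfg)), 0L)
  cfg_keep <- segmentation_config(threshold_method = "fixed",
                                  fixed_threshold = 0.5, min_area = 10L,
                                  opening_radius = 0L,
                                  border_policy = "keep")
  expect_identical(n_regions(binarize_and_label(img, cfg_keep)), 1L)
})

test_that("connected components equal a brute-force BFS labeling", {
  withr::local_seed(42)
  for (rep in 1:8) {
    mask <- matrix(runif(48 * 40) < 0.35, 48, 40)
    for (conn in c(4L, 8L)) {
      ours <- cellbright:::cb_label(mask, conn)
      ref <- bfs_label(mask, conn)
      # identical partitions up to renumbering: labels must be a bijection
      expect_identical(max(ours), max(ref))
      tab <- table(ours[mask], ref[mask])
      expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    }
  }
})

test_that("raising min_area never increases the region count", {
  fr <- generate_frame(tiny_spec(seed = 4L))
  counts <- vapply(c(1L, 50L, 200L, 600L, 2000L), function(a) {
    n_regions(binarize_and_label(
      fr$membrane, segmentation_config(min_area = a, opening_radius = 0L)))
  }, integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("Otsu threshold agrees with the EBImage reference", {
  withr::local_seed(11)
  img <- matrix(c(rnorm(600, 0.2, 0.04), rnorm(424, 0.7, 0.05)), 32, 32)
  img <- pmin(pmax(img, 0), 1)
  ours <- cellbright:::otsu_threshold(img)
  ref <- EBImage::otsu(img, range = c(0, 1), levels = 256)
  expect_equal(ours, ref, tolerance = 2 / 256)
})

test_that("region table reports centroids, areas and half-open boxes", {
  m <- matrix(0L, 30, 30)
  m[6:15, 6:15] <- 1L  # rows 5..14, cols 5..14 in 0-based coordinates
  regions <- regions_from_labelmap(as_label_map(m))
  expect_identical(regions$area, 100L)
  expect_equal(regions$row, 9.5)
  expect_equal(regions$col, 9.5)
  expect_identical(c(regions$min_row, regions$min_col,
                     regions$max_row, regions$max_col),
                   c(5L, 5L, 15L, 15L))
  # centroid lies inside the box; areas sum to nonzero pixel count
  expect_true(regions$row >= regions$min_row & regions$row < regions$max_row)
  expect_identical(sum(regions$area), sum(m > 0L))
})

test_that("region matching pairs identical, shifted and dropped regions", {
  fr <- generate_frame(tiny_spec(seed = 6L))
  lab <- fr$truth_labels
  self <- match_regions(lab, lab)
  expect_identical(nrow(self), n_regions(lab))
  expect_true(all(self$jaccard == 1))
  expect_identical(self$id_a, self$id_b)

  # delete one region from b: it stays unpaired, others self-pair
  mb <- lab$labels
  mb[mb == 2L] <- 0L
  dropped <- match_regions(lab, as_label_map(mb))
  expect_identical(nrow(dropped), n_regions(lab) - 1L)
  expect_false(2L %in% dropped$id_a)

  # shift by 2 px: large regions keep Jaccard > 0.5 and all pairs remain
  shifted <- rbind(matrix(0L, 2, ncol(lab$labels)),
                   lab$labels[1:(nrow(lab$labels) - 2), ])
  pairs <- match_regions(lab, as_label_map(shifted))
  expect_identical(nrow(pairs), n_regions(lab))
  expect_true(all(pairs$jaccard > 0.5))
  # oracle: exhaustive overlap count for one pair
  id <- pairs$id_a[1]
  ov <- sum(lab$labels == id & shifted == pairs$id_b[1])
  expect_identical(pairs$overlap[1], ov)
})

test_that("match_regions rejects mismatched dimensions", {
  a <- as_label_map(matrix(0L, 10, 10))
  b <- as_label_map(matrix(0L, 12, 10))
  expect_error(match_regions(a, b), "different dimensions")
})

test_that("noise-free synthetic frames are recovered exactly", {
  cfg <- segmentation_config(opening_radius = 0L)
  for (seed in c(10L, 11L)) {
    fr <- generate_frame(tiny_spec(seed = seed))
    lab <- binarize_and_label(fr$membrane, cfg)
    pairs <- match_regions(lab, fr$truth_labels)
    expect_identical(nrow(pairs), n_regions(fr$truth_labels))
    expect_true(all(pairs$jaccard == 1))
  }
})
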