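test_that("pearson handles perfect and hand-computed correlations", {
  x <- as.numeric(1:10)
  perfect <- pearson(x, x)
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p, 1e-12)
  expect_equal(pearson(x, -x)$r, -1)
  # hand evaluation of the covariance formula
  hand <- pearson(c(1, 2, 3), c(1, 2, 4))
  expect_equal(hand$r, 9 / sqrt(84), tolerance = 1e-12)
})

test_that("pearson matches the direct formula and cor.test", {
  withr::local_seed(5)
  for (rep in 1:20) {
    n <- sample(3:50, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- pearson(x, y)
    r_direct <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(got$r, r_direct, tolerance = 1e-12)
    ct <- stats::cor.test(x, y)
    expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p, ct$p.value, tolerance = 1e-12)
    expect_identical(got$n, n)
  }
})

test_that("pearson is affine invariant up to sign", {
  withr::local_seed(6)
  x <- rnorm(25); y <- rnorm(25)
  r0 <- pearson(x, y)$r
  expect_equal(pearson(3.2 * x + 5, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson(-0.7 * x + 1, y)$r, -r0, tolerance = 1e-12)
})

test_that("degenerate inputs raise errors", {
  expect_error(pearson(1:5, 1:4), "different lengths")
  expect_error(pearson(c(1, 2), c(3, 4)), "n >= 3")
  expect_error(pearson(rep(1, 5), rnorm(5)), "constant")
})

test_that("small-sample p-value agrees with the permutation distribution", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  got <- pearson(x, y)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  r_obs <- got$r
  r_all <- apply(perms, 1, function(p) stats::cor(x, y[p]))
  # two-sided permutation p: fraction of |r| >= |r_obs| (6 pairings);
  # only the identity ordering and its reverse reach |r| = 9/sqrt(84)
  p_perm <- mean(abs(r_all) >= abs(r_obs) - 1e-12)
  expect_equal(p_perm, 1 / 3)
  # with n = 3 both routes agree the correlation is non-significant
  expect_gt(got$p, 0.05)
  expect_gt(p_perm, 0.05)
})

test_that("evaluate_model joins on shared ids and keeps affine r = 1", {
  measured <- tibble::tibble(cell_id = 1:8, mean = runif(8))
  self <- evaluate_model(measured,
                         tibble::tibble(cell_id = 1:8,
                                        estimate = measured$mean))
  expect_equal(self$r, 1)
  scaled <- evaluate_model(measured,
                           tibble::tibble(cell_id = 1:8,
                                          estimate = 2 * measured$mean + 5))
  expect_equal(scaled$r, 1, tolerance = 1e-12)
  expect_error(
    evaluate_model(measured, tibble::tibble(cell_id = 101:108,
                                            estimate = runif(8))),
    "fewer than 3")
  # partial overlap: excluded ids are reported
  expect_message(
    evaluate_model(measured, tibble::tibble(cell_id = 4:12,
                                            estimate = runif(9))),
    "excluded")
})

test_that("scatter export round-trips and reproduces the header r", {
  withr::local_seed(8)
  measured <- tibble::tibble(cell_id = 1:5, mean = runif(5))
  est <- tibble::tibble(cell_id = 1:5,
                        estimate = measured$mean + rnorm(5, 0, 0.05))
  res <- evaluate_model(measured, est, marker_name = "m")
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- export_scatter(res, path)
  expect_identical(nrow(tab), 5L)
  lines <- readLines(path)
  expect_identical(sum(grepl("^#", lines)), 4L)
  back <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  r_re <- pearson(back$measured, back$estimate)$r
  r_hdr <- as.numeric(sub("# r: ", "", lines[grepl("^# r:", lines)]))
  expect_equal(r_re, r_hdr, tolerance = 1e-12)
  expect_equal(r_re, res$r, tolerance = 1e-12)
})

test_that("tidy and glance methods return one-row summaries", {
  res <- pearson(rnorm(10), rnorm(10), marker_name = "mk")
  td <- tidy(res)
  expect_identical(nrow(td), 1L)
  expect_named(td, c("marker", "r", "p", "n", "significant"))
})
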