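test_that("pattern construction validates coordinates, window and marks", {
  w <- rect_10x2()
  p <- point_pattern(data.frame(x = c(1, 2, 3), y = c(1, 1.5, 0.5)), w)
  expect_equal(n_points(p), 3)
  expect_false(is_marked(p))

  expect_error(
    point_pattern(data.frame(x = c(1, 11), y = c(1, 1)), w),
    "outside the observation window.*2"
  )
  expect_error(
    point_pattern(data.frame(x = c(1, 1), y = c(1, 1)), w),
    "duplicate"
  )
  expect_warning(
    point_pattern(data.frame(x = c(1, 1), y = c(1, 1)), w,
                  allow_duplicates = TRUE),
    "duplicate"
  )
  expect_error(
    point_pattern(data.frame(x = 1, y = 1, taxon = "Foo"), w,
                  levels = c("Pennatuloidea", "Cerianthidae")),
    "outside the declared label set"
  )
  # boundary points count as inside
  pb <- point_pattern(data.frame(x = c(0, 10), y = c(0, 2)), w)
  expect_equal(n_points(pb), 2)
})

test_that("nearest-neighbour summaries match hand values and the brute-force oracle", {
  w <- rect_10x2()
  p2 <- point_pattern(data.frame(x = c(1, 1.5), y = c(1, 1)), w)
  s2 <- nnd_summary(p2)
  expect_equal(s2$min, 0.5)
  expect_equal(s2$mean, 0.5)

  p3 <- point_pattern(data.frame(x = c(0, 1, 3), y = c(1, 1, 1)), w)
  s3 <- nnd_summary(p3)
  expect_equal(s3$distances, c(1, 1, 2))
  expect_equal(s3$min, 1)
  expect_equal(s3$mean, 4 / 3)

  p50 <- simulate_csr(w, n = 50, seed = 11)
  s50 <- nnd_summary(p50)
  expect_equal(s50$distances, oracle_nnd(p50$x, p50$y), tolerance = 1e-14)
  # order invariance
  shuf <- withr::with_seed(1, sample(50))
  ps <- point_pattern(data.frame(x = p50$x[shuf], y = p50$y[shuf]), w)
  expect_equal(sort(nnd_summary(ps)$distances), sort(s50$distances))

  expect_error(nnd_summary(point_pattern(data.frame(x = 1, y = 1), w)),
               "insufficient points")
})

test_that("scalar intensity is n over area", {
  w <- rect_10x2()
  expect_equal(intensity_scalar(simulate_csr(w, n = 40, seed = 1)), 2)
  expect_equal(intensity_scalar(point_pattern(
    data.frame(x = numeric(0), y = numeric(0)), w)), 0)
  w2 <- window_rect(c(0, 26.665), c(0, 2))
  expect_equal(intensity_scalar(simulate_csr(w2, n = 32, seed = 2)),
               0.6, tolerance = 1e-4)
})

test_that("subset and unmark preserve geometry", {
  w <- rect_10x2()
  p <- point_pattern(
    data.frame(x = c(1, 2, 3), y = c(1, 1, 1),
               taxon = c("A", "B", "A")), w)
  expect_equal(n_points(subset_taxon(p, "A")), 2)
  expect_equal(n_points(unmark(p)), 3)
  expect_error(subset_taxon(p, "C"), "no such mark")
})
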