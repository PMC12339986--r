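test_that("isotropic weights have the textbook values at edges and corners", {
  w <- window_rect(c(0, 10), c(0, 10))
  expect_equal(isotropic_weight(5, 5, 1, w), 1)
  expect_equal(isotropic_weight(5, 0, 0.5, w), 2)
  expect_equal(isotropic_weight(0, 0, 0.5, w), 4)
  expect_error(isotropic_weight(5, 5, -1, w), "r must be > 0")
  expect_error(isotropic_weight(20, 5, 1, w), "outside the window")
})

test_that("weights agree with the circumference-sampling oracle", {
  # rectangles (closed form path), including radii beyond half the width
  w <- rect_10x2()
  set.seed(3)
  for (k in 1:12) {
    x <- runif(1, 0, 10)
    y <- runif(1, 0, 2)
    r <- runif(1, 0.05, 1.6)
    frac <- oracle_circle_fraction(x, y, r, w, n_base = 2e5)
    expect_equal(1 / isotropic_weight(x, y, r, w), frac, tolerance = 1e-6)
  }
  # non-convex polygon (arc decomposition path)
  poly <- window_polygon(data.frame(
    x = c(0, 6, 6, 3, 3, 0),
    y = c(0, 0, 4, 4, 2, 2)
  ))
  set.seed(4)
  tries <- 0
  done <- 0
  while (done < 8 && tries < 200) {
    tries <- tries + 1
    x <- runif(1, 0, 6)
    y <- runif(1, 0, 4)
    if (!transectppa:::cpp_in_poly(x, y, poly$x, poly$y)) next
    r <- runif(1, 0.1, 1.5)
    frac <- oracle_circle_fraction(x, y, r, poly, n_base = 2e5)
    if (frac <= 0) next
    expect_equal(1 / isotropic_weight(x, y, r, poly), frac, tolerance = 1e-6)
    done <- done + 1
  }
  expect_gte(done, 8)
})
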