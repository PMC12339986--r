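test_that("the quadrat chi-squared statistic follows its arithmetic", {
  # 40 points in one of 4 equal quadrats: chi2 = 30^2/10 * 1 + 3 * 10 = 120
  w <- window_rect(c(0, 4), c(0, 4))
  set.seed(81)
  pts <- data.frame(x = runif(40, 0.05, 1.95), y = runif(40, 0.05, 1.95))
  p <- point_pattern(pts, w)
  q <- quadrat_mc_test(p, nx = 2, ny = 2, n_sim = 999, seed = 82)
  expect_equal(q$statistic, 120)
  expect_equal(q$p_value, 1 / 1000)
  expect_false(q$detail$homogeneous)
  expect_equal(q$dof, 3L)
})

test_that("the quadrat test is calibrated under CSR", {
  w <- rect_10x2()
  set.seed(83)
  rej <- mean(replicate(200, {
    p <- simulate_csr(w, n = 50)
    quadrat_mc_test(p, 3, 2, n_sim = 99)$p_value <= 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.035)
})

test_that("the quadrat test detects a strong gradient", {
  w <- rect_10x2()
  set.seed(84)
  rej <- mean(replicate(40, {
    pts <- transectppa:::gradient_points(w, 50, 0.5)
    p <- point_pattern(pts, w, allow_duplicates = TRUE)
    quadrat_mc_test(p, 3, 2, n_sim = 99)$p_value <= 0.05
  }))
  expect_gte(rej, 0.9)
})

test_that("quadrat expectations use clipped areas on polygonal windows", {
  tri <- window_polygon(data.frame(x = c(0, 8, 0), y = c(0, 0, 2)))
  p <- simulate_csr(tri, n = 60, seed = 85)
  q <- quadrat_mc_test(p, nx = 2, ny = 1, n_sim = 99, seed = 86)
  # left half of the triangle holds 3/4 of the area
  expect_equal(q$detail$expected,
               60 * c(0.75, 0.25), tolerance = 1e-10)
})

test_that("Kendall tau matches hand values and the pair-count oracle", {
  expect_equal(kendall_tau(1:8, (1:8)^2)$statistic, 1)
  expect_equal(kendall_tau(1:8, -(1:8))$statistic, -1)
  set.seed(87)
  x <- rnorm(10)
  y <- rnorm(10)
  expect_equal(kendall_tau(x, y)$statistic, oracle_kendall(x, y),
               tolerance = 1e-12)
  expect_error(kendall_tau(1:4, 1:5), "length mismatch")
})
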