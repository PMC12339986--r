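test_that("kernel intensity conserves mass after edge correction", {
  w <- rect_10x2()
  p1 <- point_pattern(data.frame(x = 0.4, y = 0.3), w)
  s1 <- kernel_intensity(p1, bandwidth = 1, grid_resolution = 0.05)
  expect_equal(surface_integral(s1), 1, tolerance = 0.02)

  p <- simulate_csr(w, n = 50, seed = 21)
  s <- kernel_intensity(p, bandwidth = 1, grid_resolution = 0.05)
  expect_equal(surface_integral(s), 50, tolerance = 0.02 * 50)
})

test_that("well-separated points give local maxima at their locations", {
  w <- rect_10x2()
  p <- point_pattern(data.frame(x = c(2, 8), y = c(1, 1)), w)
  s <- kernel_intensity(p, bandwidth = 0.3, grid_resolution = 0.05)
  v1 <- surface_at(s, 2, 1)
  v2 <- surface_at(s, 8, 1)
  vmid <- surface_at(s, 5, 1)
  expect_gt(v1, 5 * vmid)
  expect_gt(v2, 5 * vmid)
})

test_that("uniform patterns give a near-flat central surface", {
  w <- rect_10x2()
  set.seed(31)
  vals <- replicate(10, {
    p <- simulate_csr(w, n = 500)
    s <- kernel_intensity(p, bandwidth = 1, grid_resolution = 0.1)
    central <- s$value[s$x > 1 & s$x < 9 & s$y > 0.5 & s$y < 1.5]
    mean(central)
  })
  expect_equal(mean(vals), 25, tolerance = 0.15 * 25)
})

test_that("constant Poisson fit matches the closed form", {
  w <- rect_10x2()
  p <- simulate_csr(w, n = 40, seed = 5)
  f <- fit_poisson(p)
  lam <- 40 / 20
  expect_equal(unname(f$coefficients[1]), log(lam), tolerance = 1e-10)
  expect_equal(f$logLik, 40 * log(lam) - 40, tolerance = 1e-8)
  expect_equal(f$aic, 2 - 2 * f$logLik)
})

test_that("quadrature refinement barely changes the constant log-likelihood", {
  w <- rect_10x2()
  p <- simulate_csr(w, n = 45, seed = 6)
  f1 <- fit_poisson(p, grid_resolution = 0.1)
  f2 <- fit_poisson(p, grid_resolution = 0.05)
  expect_lt(abs(f1$logLik - f2$logLik), 0.1)
})

test_that("a log-linear x gradient is recovered", {
  w <- rect_10x2()
  set.seed(8)
  slopes <- replicate(8, {
    sc <- transectppa:::gradient_points(w, 400, 0.5)
    p <- point_pattern(sc, w, allow_duplicates = TRUE)
    unname(fit_poisson(p, "x", grid_resolution = 0.1)$coefficients["x"])
  })
  expect_equal(mean(slopes), 0.5, tolerance = 0.15)
})

test_that("AIC prefers the constant model on homogeneous patterns", {
  w <- rect_10x2()
  set.seed(9)
  wins <- mean(replicate(40, {
    p <- simulate_csr(w, n = 60)
    fit_poisson(p, grid_resolution = 0.1)$aic <
      fit_poisson(p, "x", grid_resolution = 0.1)$aic
  }))
  expect_gte(wins, 0.7)
})

test_that("kernel intensity is translation-equivariant", {
  w <- rect_10x2()
  p <- simulate_csr(w, n = 30, seed = 10)
  s <- kernel_intensity(p, 1, 0.1)
  w2 <- window_rect(c(3, 13), c(1, 3))
  p2 <- point_pattern(data.frame(x = p$x + 3, y = p$y + 1), w2,
                      allow_duplicates = TRUE)
  s2 <- kernel_intensity(p2, 1, 0.1)
  expect_equal(s2$value, s$value, tolerance = 1e-10)
})
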