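test_that("L is close to r under CSR", {
  w <- window_rect(c(0, 20), c(0, 20))
  p <- simulate_csr(w, n = 2000, seed = 31)
  l <- l_function(p, r_max = 1, n_grid = 128)
  expect_lt(max(abs(l$value - l$r)), 0.05)
})

test_that("K matches the weighted pair-count oracle exactly", {
  p <- toy_pattern()
  k <- k_function(p, r_max = 1, n_grid = 32)
  expect_equal(k$value, oracle_k(p, k$r), tolerance = 1e-12)
  l <- l_function(p, r_max = 1, n_grid = 32)
  expect_equal(l$value, sqrt(oracle_k(p, k$r) / pi), tolerance = 1e-12)
})

test_that("hard-core patterns have L = 0 below the core distance", {
  w <- rect_10x2()
  p <- simulate_gibbs(w, 40, "hardcore", hc_radius = 0.3, n_sweeps = 2e4,
                      seed = 32)
  l <- l_function(p, r_max = 1, n_grid = 128)
  expect_true(all(l$value[l$r < 0.3] == 0))
})

test_that("differentiating K recovers the PCF on clustered patterns", {
  w <- window_rect(c(0, 15), c(0, 15))
  p <- simulate_thomas(5, 0.1, 8, w, seed = 33)
  g <- pcf(p, r_max = 0.6, n_grid = 128)
  k <- k_function(p, r_max = 0.6, n_grid = 128)
  dk <- diff(k$value) / diff(k$r)
  g_from_k <- dk / (2 * pi * k$r[-1])
  sel <- k$r[-1] >= 0.05 & k$r[-1] <= 0.5
  expect_gt(stats::cor(g_from_k[sel], g$value[-1][sel]), 0.95)
})

test_that("cross-K counts only cross pairs", {
  w <- rect_10x2()
  # two types at fixed separations: A at x, B displaced 0.3 to the right
  xa <- seq(1, 9, by = 1)
  p <- point_pattern(
    data.frame(x = c(xa, xa + 0.3), y = rep(1, 18),
               taxon = rep(c("A", "B"), each = 9)), w,
    allow_duplicates = TRUE)
  k <- k_cross(p, "A", "B", r_max = 0.5, n_grid = 50)
  # below 0.3 no cross pairs; at 0.3 every A has one B at distance 0.3
  expect_true(all(k$value[k$r < 0.3] == 0))
  expect_gt(k$value[which.min(abs(k$r - 0.35))], 0)
})
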