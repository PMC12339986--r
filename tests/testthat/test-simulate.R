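test_that("CSR simulation honours count, window and seed", {
  w <- rect_10x2()
  p <- simulate_csr(w, n = 50, seed = 41)
  expect_equal(n_points(p), 50)
  expect_true(all(p$x >= 0 & p$x <= 10 & p$y >= 0 & p$y <= 2))
  p2 <- simulate_csr(w, n = 50, seed = 41)
  expect_identical(p$x, p2$x)

  set.seed(42)
  counts <- replicate(400, n_points(simulate_csr(w, intensity = 2.5)))
  expect_equal(mean(counts), 50, tolerance = 2 / 50 * 3)

  # polygonal window: rejection sampling stays inside
  tri <- window_polygon(data.frame(x = c(0, 8, 0), y = c(0, 0, 3)))
  pt <- simulate_csr(tri, n = 40, seed = 43)
  expect_true(all(transectppa:::cpp_in_poly(pt$x, pt$y, tri$x, tri$y)))
})

test_that("Thomas simulation has the Neyman-Scott intensity", {
  w <- rect_10x2()
  set.seed(44)
  counts <- replicate(300, n_points(simulate_thomas(2, 0.05, 5, w)))
  expect_equal(mean(counts), 200, tolerance = 10)
})

test_that("Thomas offspring collapse onto parents as sigma goes to 0", {
  w <- rect_10x2()
  p <- simulate_thomas(1, 1e-7, 5, w, seed = 45)
  nn <- nnd_summary(p)
  # distances are either ~0 (same cluster) or macroscopic (between clusters)
  expect_true(all(nn$distances < 1e-5 | nn$distances > 1e-3))
})

test_that("linked Thomas marginals behave and an empty type is allowed", {
  w <- rect_10x2()
  p <- simulate_linked_thomas(0.5, 0.1, c(A = 6, B = 1e-9), w, seed = 46)
  expect_equal(n_points(subset_taxon(p, "B")), 0)
  expect_gt(n_points(subset_taxon(p, "A")), 0)
})

test_that("hard-core output never violates the core distance", {
  w <- rect_10x2()
  for (s in 1:10) {
    p <- simulate_gibbs(w, 40, "hardcore", hc_radius = 0.25,
                        n_sweeps = 5e3, seed = 100 + s)
    expect_gte(nnd_summary(p)$min, 0.25)
  }
  expect_error(
    simulate_gibbs(w, 500, "hardcore", hc_radius = 0.5),
    "infeasible packing"
  )
})

test_that("small sc_kappa approaches hard-core behaviour", {
  w <- rect_10x2()
  set.seed(47)
  viol <- mean(replicate(40, {
    p <- simulate_gibbs(w, 40, "softcore", sc_sigma = 0.2, sc_kappa = 0.1,
                        n_sweeps = 5e3)
    nnd_summary(p)$min < 0.1
  }))
  expect_lt(viol, 0.05)
})

test_that("soft-core patterns are inhibited at small distances", {
  w <- rect_10x2()
  set.seed(48)
  gvals <- replicate(10, {
    p <- simulate_gibbs(w, 60, "softcore", sc_sigma = 0.2, sc_kappa = 0.5,
                        n_sweeps = 1e4)
    g <- pcf(p, r_max = 1, n_grid = 64)
    mean(g$value[g$r > 0.05 & g$r < 0.2], na.rm = TRUE)
  })
  expect_lt(mean(gvals), 1)
})

test_that("doubling the chain length leaves mean NND stable", {
  w <- rect_10x2()
  set.seed(49)
  m1 <- mean(replicate(30, {
    nnd_summary(simulate_gibbs(w, 40, "softcore", sc_sigma = 0.2,
                               sc_kappa = 0.5, n_sweeps = 1e4))$mean
  }))
  m2 <- mean(replicate(30, {
    nnd_summary(simulate_gibbs(w, 40, "softcore", sc_sigma = 0.2,
                               sc_kappa = 0.5, n_sweeps = 2e4))$mean
  }))
  expect_lt(abs(m1 - m2) / m1, 0.05)
})
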