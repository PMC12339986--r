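test_that("the PCF of a large CSR pattern is near 1", {
  w <- window_rect(c(0, 20), c(0, 20))
  p <- simulate_csr(w, n = 2000, seed = 101)
  g <- pcf(p, r_max = 2, n_grid = 256)
  sel <- g$r >= 0.5 & g$r <= 2
  expect_lt(mean(abs(g$value[sel] - 1)), 0.05)
})

test_that("the PCF matches the direct-summation oracle on a toy pattern", {
  p <- toy_pattern()
  bw <- 0.25
  g <- pcf(p, r_max = 1, bw = bw, n_grid = 64)
  expected <- oracle_pcf(p, g$r, bw)
  expect_equal(g$value[-1], expected[-1], tolerance = 1e-10)
})

test_that("the inhomogeneous PCF reduces to the PCF for constant intensity", {
  w <- rect_10x2()
  p <- simulate_csr(w, n = 40, seed = 12)
  g <- pcf(p, r_max = 1, n_grid = 128)
  lam <- n_points(p) / w$area
  gr <- transectppa:::make_grid(w, 0.1)
  const <- structure(
    tibble::tibble(x = gr$x, y = gr$y, value = rep(lam, length(gr$x))),
    window = w, bandwidth = NA_real_, cell_area = gr$cell_area,
    grid_resolution = 0.1, kernel = "constant", edge_correct = NA, n = 40,
    class = c("intensity_surface", "tbl_df", "tbl", "data.frame")
  )
  gi <- pcf_inhom(p, const, r_max = 1, n_grid = 128)
  expect_equal(gi$value[-1], g$value[-1], tolerance = 1e-9)
})

test_that("the PCF of Thomas simulations matches the closed form", {
  # small-scale version of the closed-form check (the acceptance suite runs
  # the full 30 x 30 m, 20-replicate version)
  w <- window_rect(c(0, 15), c(0, 15))
  set.seed(13)
  devs <- replicate(5, {
    p <- simulate_thomas(5, 0.1, 8, w)
    g <- pcf(p, r_max = 0.6, n_grid = 128)
    sel <- g$r >= 0.05 & g$r <= 0.5
    th <- thomas_pcf(g$r[sel], 5, 0.1)
    mean((g$value[sel] - th) / th)
  })
  expect_lt(abs(mean(devs)), 0.1)
})

test_that("cross-PCF is symmetric and near 1 for independent CSR types", {
  w <- rect_10x2()
  set.seed(14)
  curves <- replicate(12, {
    a <- transectppa:::runif_window(w, 50)
    b <- transectppa:::runif_window(w, 50)
    p <- point_pattern(
      data.frame(x = c(a$x, b$x), y = c(a$y, b$y),
                 taxon = rep(c("A", "B"), each = 50)), w,
      allow_duplicates = TRUE)
    pcf_cross(p, "A", "B", r_max = 1, n_grid = 64)$value
  })
  gbar <- rowMeans(curves)
  r <- seq(0, 1, length.out = 65)
  expect_lt(mean(abs(gbar[r >= 0.3] - 1)), 0.07)

  set.seed(15)
  a <- transectppa:::runif_window(w, 30)
  b <- transectppa:::runif_window(w, 25)
  p <- point_pattern(
    data.frame(x = c(a$x, b$x), y = c(a$y, b$y),
               taxon = c(rep("A", 30), rep("B", 25))), w,
    allow_duplicates = TRUE)
  g12 <- pcf_cross(p, "A", "B", r_max = 1, n_grid = 64)
  g21 <- pcf_cross(p, "B", "A", r_max = 1, n_grid = 64)
  expect_equal(g12$value[-1], g21$value[-1], tolerance = 1e-10)
})

test_that("linked Thomas types are cross-clustered at small distances", {
  w <- rect_10x2()
  set.seed(16)
  vals <- replicate(8, {
    p <- simulate_linked_thomas(0.5, 0.1, c(A = 6, B = 6), w)
    if (n_points(subset_taxon(p, "A")) < 5 ||
        n_points(subset_taxon(p, "B")) < 5) return(NA_real_)
    g <- pcf_cross(p, "A", "B", r_max = 1, n_grid = 64)
    mean(g$value[g$r >= 0.05 & g$r <= 0.2], na.rm = TRUE)
  })
  expect_gt(mean(vals, na.rm = TRUE), 2)
})

test_that("r_max beyond the scale rule is refused unless overridden", {
  w <- rect_10x2()
  p <- simulate_csr(w, n = 40, seed = 17)
  expect_error(pcf(p, r_max = 1.5), "exceeds half the shortest")
  expect_silent(pcf(p, r_max = 1.5, override_scale = TRUE))
})

test_that("estimators are invariant to point order and rigid motions", {
  w <- rect_10x2()
  p <- simulate_csr(w, n = 40, seed = 18)
  g0 <- pcf(p, r_max = 1, n_grid = 64)
  shuf <- withr::with_seed(2, sample(40))
  ps <- point_pattern(data.frame(x = p$x[shuf], y = p$y[shuf]), w,
                      allow_duplicates = TRUE)
  expect_equal(pcf(ps, r_max = 1, n_grid = 64)$value, g0$value,
               tolerance = 1e-12)
  # translation of pattern and window together
  w2 <- window_rect(c(5, 15), c(2, 4))
  p2 <- point_pattern(data.frame(x = p$x + 5, y = p$y + 2), w2,
                      allow_duplicates = TRUE)
  expect_equal(pcf(p2, r_max = 1, n_grid = 64)$value, g0$value,
               tolerance = 1e-10)
})
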