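fake_envelope <- function(r, obs, lo, hi, bw = 0) {
  out <- structure(
    tibble::tibble(r = r, obs = obs, lo = lo, hi = hi,
                   reliable = rep(TRUE, length(r))),
    n_sim = 999, rank = 49, model_family = "csr", variant = "pcf",
    bandwidth = bw, window = rect_10x2(),
    class = c("envelope_result", "tbl_df", "tbl", "data.frame")
  )
  attr(out, "excursions") <- transectppa:::extract_excursions(out)
  out
}

fake_quadrat <- function(homogeneous) {
  transectppa:::ppa_test("quadrat_mc", 10, 5L, if (homogeneous) 0.5 else 0.01,
                         99, detail = list(homogeneous = homogeneous))
}

test_that("classification labels follow the excursion pattern", {
  r <- seq(0, 1, length.out = 101)
  inside <- fake_envelope(r, rep(1, 101), rep(0.5, 101), rep(1.5, 101))
  c0 <- classify_pattern(inside, fake_quadrat(TRUE))
  expect_equal(c0$label, "csr")

  obs <- rep(1, 101)
  obs[r >= 0.3 & r <= 0.6] <- 2
  c1 <- classify_pattern(fake_envelope(r, obs, rep(0.5, 101), rep(1.5, 101)),
                         fake_quadrat(TRUE))
  expect_equal(c1$label, "clustered")
  expect_equal(c1$excursions$r_start[1], 0.3)
  expect_equal(c1$excursions$r_end[1], 0.6)

  obs2 <- rep(1, 101)
  obs2[r <= 0.2] <- 3
  obs2[r >= 0.55 & r <= 0.65] <- 0.1
  c2 <- classify_pattern(fake_envelope(r, obs2, rep(0.5, 101), rep(1.5, 101)),
                         fake_quadrat(TRUE))
  expect_equal(c2$label, "mixed")
  expect_setequal(c2$excursions$direction, c("above", "below"))
})

test_that("narrow grazes at kernel scale do not flip the label", {
  r <- seq(0, 1, length.out = 101)
  obs <- rep(1, 101)
  obs[50] <- 2                      # single-point graze
  obs[70:71] <- 2                   # two-point graze, width 0.02 < bw
  e <- fake_envelope(r, obs, rep(0.5, 101), rep(1.5, 101), bw = 0.1)
  cl <- classify_pattern(e, fake_quadrat(TRUE))
  expect_equal(cl$label, "csr")
  expect_true(all(!cl$excursions$significant))
})

test_that("patterns below the 30-point filter are excluded with a reason", {
  w <- rect_10x2()
  p <- simulate_csr(w, n = 29, seed = 96)
  cfg <- sppa_config(n_sim = 49, seed = 1)
  rep <- run_transect_analysis(p, cfg)
  u <- rep$univariate[[1]]
  expect_equal(u$status, "excluded")
  expect_match(u$reason, "minimum of 30 points")
})

test_that("the ladder is seed-deterministic", {
  sc <- generate_scenario(scenario_spec("reproductive_dispersal", seed = 97,
                                        window_length = 10))
  cfg <- sppa_config(n_sim = 49, n_sim_gof = 49, n_sim_quadrat = 49,
                     grid_resolution = 0.1, dummy_spacing = 0.2,
                     pcf_n_grid = 64, gof_n_grid = 32, seed = 11)
  t1 <- tidy(run_transect_analysis(sc$pattern, cfg))
  t2 <- tidy(run_transect_analysis(sc$pattern, cfg))
  expect_identical(t1, t2)
})

test_that("CSR scenarios get no driver and no model fits", {
  sc <- generate_scenario(scenario_spec("csr", seed = 98, window_length = 10))
  cfg <- sppa_config(n_sim = 99, n_sim_gof = 49, n_sim_quadrat = 49,
                     grid_resolution = 0.1, dummy_spacing = 0.2,
                     pcf_n_grid = 64, gof_n_grid = 32, seed = 12)
  rep <- run_transect_analysis(sc$pattern, cfg)
  for (u in rep$univariate) {
    if (u$classification$label == "csr") {
      expect_null(u$fits)
      expect_equal(u$verdict$driver, "no_departure_from_csr")
    }
  }
})

test_that("driver mapping follows the model-to-driver table", {
  expect_equal(transectppa:::family_driver("hetero_poisson"),
               "habitat_association")
  expect_equal(transectppa:::family_driver("thomas"), "reproductive_dispersal")
  expect_equal(transectppa:::family_driver("thomas_inhom"),
               "reproductive_dispersal_with_habitat")
  expect_equal(transectppa:::family_driver("softcore"), "competition")
  expect_equal(transectppa:::family_driver("hardcore"), "competition")
  expect_equal(transectppa:::family_driver("linked_thomas"), "facilitation")
})

test_that("the bivariate overdispersion rule separates habitat from repulsion", {
  r <- seq(0, 1, length.out = 101)
  below <- rep(1, 101)
  below[r >= 0.05 & r <= 0.3] <- 0.01
  biv_env <- fake_envelope(r, below, rep(0.5, 101), rep(1.5, 101))
  biv_cls <- classify_pattern(biv_env, fake_quadrat(TRUE))
  flat <- fake_envelope(r, rep(1, 101), rep(0.5, 101), rep(1.5, 101))
  sc <- generate_scenario(scenario_spec("competition", seed = 99,
                                        window_length = 10))
  cfg <- sppa_config(n_sim = 49, grid_resolution = 0.1)
  # neither taxon overdispersed alone -> competition
  v1 <- bivariate_driver(sc$pattern, "Pennatuloidea", "Cerianthidae",
                         biv_cls, list(Pennatuloidea = flat,
                                       Cerianthidae = flat), cfg)
  expect_equal(v1$driver, "competition")
  # overlapping univariate overdispersion -> habitat-driven
  uni_below <- fake_envelope(r, below, rep(0.5, 101), rep(1.5, 101))
  v2 <- bivariate_driver(sc$pattern, "Pennatuloidea", "Cerianthidae",
                         biv_cls, list(Pennatuloidea = uni_below,
                                       Cerianthidae = flat), cfg)
  expect_equal(v2$driver, "habitat_association")
})
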