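test_that("scenario generation is seed-deterministic", {
  s1 <- generate_scenario(scenario_spec("facilitation", seed = 101))
  s2 <- generate_scenario(scenario_spec("facilitation", seed = 101))
  expect_identical(s1$pattern$x, s2$pattern$x)
  expect_identical(s1$pattern$taxon, s2$pattern$taxon)
})

test_that("conditional scenarios realise exact counts and others stay in band", {
  s <- generate_scenario(scenario_spec("csr", n_per_taxon = 50, seed = 102))
  expect_equal(unname(table(s$pattern$taxon)), c(50L, 50L),
               ignore_attr = TRUE)
  for (drv in c("reproductive_dispersal", "facilitation", "competition")) {
    sc <- generate_scenario(scenario_spec(drv, n_per_taxon = 60, seed = 103))
    counts <- tabulate(sc$pattern$taxon, 2)
    expect_true(all(counts >= 48 & counts <= 72), info = drv)
  }
})

test_that("suites are balanced with reproducible manifests", {
  s1 <- scenario_suite(3, base_seed = 104, window_length = 10)
  expect_equal(nrow(s1$manifest), 18)
  expect_equal(unname(table(s1$manifest$driver)), rep(3L, 6),
               ignore_attr = TRUE)
  s2 <- scenario_suite(3, base_seed = 104, window_length = 10)
  expect_identical(s1$manifest, s2$manifest)
})

test_that("suite nearest-neighbour distances match the study's range", {
  s <- scenario_suite(2, base_seed = 105, window_length = 10)
  mean_nnd <- vapply(s$scenarios, function(sc) {
    nnd_summary(unmark(sc$pattern))$mean
  }, numeric(1))
  min_nnd <- vapply(s$scenarios, function(sc) {
    nnd_summary(unmark(sc$pattern))$min
  }, numeric(1))
  expect_true(all(mean_nnd >= 0.04 & mean_nnd <= 0.7))
  expect_true(all(min_nnd <= 0.3))
})

test_that("habitat scenarios are detectably inhomogeneous", {
  set.seed(106)
  rej <- mean(vapply(1:20, function(i) {
    sc <- generate_scenario(scenario_spec("habitat_association",
                                          seed = 2000 + i,
                                          window_length = 10))
    p <- subset_taxon(sc$pattern, "Pennatuloidea")
    quadrat_mc_test(p, 3, 2, n_sim = 99)$p_value <= 0.05
  }, logical(1)))
  expect_gte(rej, 0.8)
})

test_that("window lengths follow the transect-length distribution", {
  lens <- vapply(1:20, function(i) {
    sc <- generate_scenario(scenario_spec("csr", seed = 3000 + i))
    b <- pattern_window(sc$pattern)$bbox
    unname(b["xmax"] - b["xmin"])
  }, numeric(1))
  expect_true(all(lens > 8))
  expect_equal(mean(lens), 11.16, tolerance = 0.05 * 11.16)
})
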