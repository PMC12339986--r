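test_that("the profiled hard-core radius is the minimum NND", {
  w <- rect_10x2()
  p <- simulate_gibbs(w, 40, "hardcore", hc_radius = 0.25, n_sweeps = 5e3,
                      seed = 61)
  f <- fit_gibbs(p, "hardcore", dummy_spacing = 0.15)
  expect_equal(f$hc_radius, nnd_summary(p)$min)
  expect_false(f$flagged)
})

test_that("soft-core parameters are recovered when the data identify them", {
  # sc_kappa is weakly identified at transect sample sizes (n ~ 60); this
  # checks estimator consistency at a density where the profile is
  # informative, plus the sc_sigma scale at transect n
  w <- rect_10x2()
  set.seed(62)
  est <- t(replicate(10, {
    p <- simulate_gibbs(w, 150, "softcore", sc_sigma = 0.2, sc_kappa = 0.5,
                        n_sweeps = 2e4)
    f <- fit_gibbs(p, "softcore", dummy_spacing = 0.1)
    c(f$sc_kappa, f$sc_sigma)
  }))
  expect_gte(mean(abs(est[, 1] - 0.5) <= 0.2), 0.6)
  expect_lt(abs(stats::median(est[, 2]) - 0.2), 0.1)
})

test_that("CSR data yields a near-null soft-core interaction", {
  w <- rect_10x2()
  set.seed(63)
  sig <- replicate(10, {
    fit_gibbs(simulate_csr(w, n = 60), "softcore",
              dummy_spacing = 0.15)$sc_sigma
  })
  expect_gte(mean(sig < 0.02), 0.5)
})

test_that("the pseudo-AIC follows its definition", {
  w <- rect_10x2()
  p <- simulate_gibbs(w, 40, "hardcore", hc_radius = 0.2, n_sweeps = 5e3,
                      seed = 64)
  f <- fit_gibbs(p, "hardcore", dummy_spacing = 0.15)
  expect_equal(f$pseudo_aic, 2 * f$k - 2 * f$logPL)
})
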