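test_that("the contrast optimiser has a zero-contrast fixed point", {
  # feed the exact closed-form K: the optimiser must return the generating
  # parameters (kappa = 3, sigma = 0.08) to high accuracy
  r <- seq(0.004, 1, length.out = 256)
  kv <- thomas_K(r, 3, 0.08)
  dr <- r[2] - r[1]
  contrast_fn <- function(par) {
    sum((kv^0.25 - thomas_K(r, exp(par[1]), exp(par[2]))^0.25)^2) * dr
  }
  starts <- expand.grid(log_kappa = log(c(0.5, 3, 10)),
                        log_sigma = log(c(0.02, 0.1, 0.3)))
  best <- transectppa:::thomas_contrast_optim(contrast_fn, starts, 1)
  expect_equal(exp(best$par[1]), 3, tolerance = 1e-4)
  expect_equal(exp(best$par[2]), 0.08, tolerance = 1e-4)
})

test_that("Thomas parameters are recovered at transect scale", {
  w <- rect_10x2()
  set.seed(51)
  est <- t(replicate(12, {
    p <- simulate_thomas(1, 0.05, 3, w)
    f <- fit_thomas(p, r_max = 1)
    c(f$kappa, f$sigma)
  }))
  expect_lt(abs(stats::median(est[, 1]) - 1) / 1, 0.3)
  expect_lt(abs(stats::median(est[, 2]) - 0.05) / 0.05, 0.3)
})

test_that("CSR input yields a flagged Thomas fit", {
  w <- rect_10x2()
  set.seed(52)
  flags <- replicate(10, fit_thomas(simulate_csr(w, n = 60), r_max = 1)$flagged)
  expect_gte(mean(flags), 0.5)
})

test_that("linked Thomas fit recovers shared-parent structure", {
  w <- rect_10x2()
  set.seed(53)
  sig <- replicate(8, {
    p <- simulate_linked_thomas(0.5, 0.12, c(A = 6, B = 6), w)
    f <- fit_linked_thomas(p, "A", "B", r_max = 1)
    if (f$flagged) NA_real_ else f$sigma
  })
  expect_lt(abs(stats::median(sig, na.rm = TRUE) - 0.12), 0.1)
})

test_that("model ranking respects families and shortlist size", {
  w <- rect_10x2()
  p <- simulate_csr(w, n = 60, seed = 54)
  f1 <- fit_poisson(p, "x", 0.1)
  f2 <- fit_poisson(p, "y", 0.1)
  f3 <- fit_poisson(p, "x+y", 0.1)
  ft <- fit_thomas(p, r_max = 1)
  ranked <- rank_models(list(f1, f2, f3, ft), top_per_family = 2)
  # within-family ordering by criterion
  pois <- ranked[ranked$family == "hetero_poisson", ]
  expect_true(all(diff(pois$criterion) >= 0))
  # families never interleaved: shortlist has at most 2 per family
  sl <- ranked[ranked$shortlisted, ]
  expect_true(all(table(sl$family) <= 2))
  expect_equal(nrow(sl),
               sum(pmin(2, table(ranked$family[!ranked$flagged]))))
  expect_error(rank_models(list()), "no fits")
})

test_that("simulating a fitted Thomas model reproduces its count scale", {
  w <- rect_10x2()
  p <- simulate_thomas(1, 0.1, 3, w, seed = 55)
  f <- fit_thomas(p, r_max = 1)
  set.seed(56)
  counts <- replicate(40, n_points(simulate(f)))
  expect_equal(mean(counts), n_points(p), tolerance = 0.25 * n_points(p))
})
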