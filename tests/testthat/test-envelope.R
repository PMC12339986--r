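test_that("envelope limits bracket the simulated median and obey ordering", {
  w <- rect_10x2()
  p <- simulate_csr(w, n = 50, seed = 71)
  e <- envelope(p, function(pp) pcf(pp, r_max = 1, n_grid = 64),
                n_sim = 99, seed = 72)
  ok <- e$reliable & is.finite(e$lo)
  expect_true(all(e$lo[ok] <= e$hi[ok]))
  # under the true model the limits should bracket the CSR reference g = 1
  # over most reliable distances
  expect_gt(mean(e$lo[ok] <= 1 & 1 <= e$hi[ok]), 0.9)
})

test_that("excursion extraction reproduces the pointwise comparison", {
  w <- rect_10x2()
  p <- simulate_thomas(1, 0.08, 3, w, seed = 73)
  e <- envelope(p, function(pp) pcf(pp, r_max = 1, n_grid = 64),
                n_sim = 99, seed = 74)
  exc <- attr(e, "excursions")
  outside <- e$reliable & is.finite(e$lo) & (e$obs > e$hi | e$obs < e$lo)
  # every r flagged outside lies in some excursion interval, and vice versa
  in_exc <- rep(FALSE, nrow(e))
  for (i in seq_len(nrow(exc))) {
    in_exc <- in_exc | (e$r >= exc$r_start[i] & e$r <= exc$r_end[i])
  }
  expect_equal(which(outside), which(outside & in_exc))
  expect_true(all(in_exc[outside]))
})

test_that("a Thomas pattern breaks the CSR envelope at cluster scale", {
  w <- rect_10x2()
  set.seed(75)
  hits <- replicate(10, {
    p <- simulate_thomas(1, 0.05, 3, w)
    e <- envelope(p, function(pp) pcf(pp, r_max = 1, n_grid = 64), n_sim = 99)
    exc <- attr(e, "excursions")
    any(exc$direction == "above" & exc$r_start <= 0.2)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("envelopes are seed-deterministic and rank-scaled", {
  w <- rect_10x2()
  p <- simulate_csr(w, n = 40, seed = 76)
  stat <- function(pp) pcf(pp, r_max = 1, n_grid = 64)
  e1 <- envelope(p, stat, n_sim = 49, seed = 77)
  e2 <- envelope(p, stat, n_sim = 49, seed = 77)
  expect_identical(e1$lo, e2$lo)
  expect_identical(e1$hi, e2$hi)
  expect_equal(transectppa:::scaled_envelope_rank(999), 49L)
  expect_equal(transectppa:::scaled_envelope_rank(99), 4L)
  expect_equal(transectppa:::scaled_envelope_rank(199), 9L)
})

test_that("DCLF returns p = 1 when the observed statistic equals the reference", {
  w <- rect_10x2()
  p <- simulate_csr(w, n = 40, seed = 78)
  # constant statistic: every curve identical, u_obs = u_sim = 0, ties
  const_stat <- function(pp) {
    transectppa:::fn_estimate(seq(0, 1, length.out = 33), rep(2, 33),
                              "const", NA_real_, 1, w, n_points(pp),
                              rep(TRUE, 33))
  }
  d <- dclf_test(p, csr_model(p), r_max = 1, n_sim = 49,
                 statistic = const_stat, seed = 79)
  expect_equal(d$p_value, 1)
  expect_equal(d$statistic, 0)
})

test_that("DCLF rejects CSR on clustered data", {
  w <- rect_10x2()
  set.seed(80)
  ps <- replicate(5, {
    p <- simulate_thomas(1, 0.05, 3, w)
    dclf_test(p, csr_model(p), r_max = 1, n_sim = 99, n_grid = 64)$p_value
  })
  expect_gte(mean(ps <= 0.05), 0.8)
})
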