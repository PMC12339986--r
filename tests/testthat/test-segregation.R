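test_that("the overall segregation statistic has 2 degrees of freedom", {
  w <- rect_10x2()
  sc <- generate_scenario(scenario_spec("csr", seed = 91, window_length = 10))
  res <- nn_segregation_test(sc$pattern, n_sim = 99, seed = 92)
  expect_equal(res$overall$dof, 2L)
  expect_length(res$per_type, 2)
  expect_true(all(vapply(res$per_type, function(t) t$dof, integer(1)) == 1L))
})

test_that("segregation test is calibrated under random labelling", {
  w <- rect_10x2()
  set.seed(93)
  rej <- mean(replicate(120, {
    xy <- transectppa:::runif_window(w, 60)
    p <- point_pattern(
      data.frame(x = xy$x, y = xy$y,
                 taxon = sample(rep(c("A", "B"), each = 30))), w,
      allow_duplicates = TRUE)
    nn_segregation_test(p, n_sim = 99)$overall$p_value <= 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.045)
})

test_that("types confined to disjoint halves segregate decisively", {
  w <- rect_10x2()
  set.seed(94)
  a <- data.frame(x = runif(30, 0, 4.5), y = runif(30, 0, 2))
  b <- data.frame(x = runif(30, 5.5, 10), y = runif(30, 0, 2))
  p <- point_pattern(
    data.frame(x = c(a$x, b$x), y = c(a$y, b$y),
               taxon = rep(c("A", "B"), each = 30)), w,
    allow_duplicates = TRUE)
  res <- nn_segregation_test(p, n_sim = 999, seed = 95)
  expect_lte(res$overall$p_value, 0.01)
})

test_that("segregation requires exactly two sufficiently large types", {
  w <- rect_10x2()
  p <- point_pattern(
    data.frame(x = 1:6, y = rep(1, 6), taxon = rep(c("A", "B"), 3)), w)
  expect_error(nn_segregation_test(p), "at least 5")
  p1 <- point_pattern(data.frame(x = 1:6, y = rep(1, 6),
                                 taxon = rep("A", 6)), w)
  expect_error(nn_segregation_test(p1), "exactly 2")
})
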