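#' Monte-Carlo quadrat test of inhomogeneity
#'
#' The window is partitioned into an `nx` by `ny` grid of equal rectangles
#' (clipped to the polygon); the chi-squared statistic
#' `sum (O_i - E_i)^2 / E_i`, with expectations proportional to clipped
#' quadrat area, is compared against its Monte-Carlo distribution under CSR
#' conditional on n. Under conditional CSR the vector of quadrat counts is
#' exactly multinomial with probabilities proportional to quadrat areas, so
#' the reference counts are drawn directly from that multinomial. A p-value
#' above 0.05 is taken to indicate homogeneity.
#'
#' @param pattern A `point_pattern` with `n >= 1`.
#' @param nx,ny Quadrat grid (default 3 x 2: slender transect windows, chosen
#'   so expected counts stay near or above 5 at n = 30).
#' @param n_sim Number of Monte-Carlo draws.
#' @param seed Optional integer seed.
#' @return A `ppa_test` with the chi-squared `statistic`, Monte-Carlo
#'   `p_value`, and `detail$homogeneous = p > 0.05`.
#' @export
quadrat_mc_test <- function(pattern, nx = 3, ny = 2, n_sim = 999,
                            seed = NULL) {
  n <- n_points(pattern)
  if (n < 1) stop("empty pattern", call. = FALSE)
  if (nx * ny < 2) stop("need at least 2 quadrats", call. = FALSE)
  w <- pattern_window(pattern)
  b <- w$bbox
  xs <- seq(b["xmin"], b["xmax"], length.out = nx + 1)
  ys <- seq(b["ymin"], b["ymax"], length.out = ny + 1)
  cells <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  areas <- vapply(seq_len(nrow(cells)), function(k) {
    if (w$is_rect) {
      (xs[2] - xs[1]) * (ys[2] - ys[1])
    } else {
      clipped_area(w, xs[cells$ix[k]], xs[cells$ix[k] + 1],
                   ys[cells$iy[k]], ys[cells$iy[k] + 1])
    }
  }, numeric(1))
  if (any(areas <= 0)) {
    warning("dropping quadrats with zero clipped area", call. = FALSE)
    keep <- areas > 0
  } else {
    keep <- rep(TRUE, length(areas))
  }
  ix <- pmin(nx, pmax(1, findInterval(pattern$x, xs, rightmost.closed = TRUE)))
  iy <- pmin(ny, pmax(1, findInterval(pattern$y, ys, rightmost.closed = TRUE)))
  cell_of <- (iy - 1) * nx + ix
  counts <- tabulate(cell_of, nbins = nx * ny)[keep]
  areas <- areas[keep]
  prob <- areas / sum(areas)
  expected <- n * prob
  chisq <- function(o) sum((o - expected)^2 / expected)
  obs <- chisq(counts)
  run <- function() {
    sims <- stats::rmultinom(n_sim, n, prob)
    sim_stats <- colSums((sims - expected)^2 / expected)
    (1 + sum(sim_stats >= obs)) / (n_sim + 1)
  }
  p <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  ppa_test(
    name = "quadrat_mc",
    statistic = obs, dof = sum(keep) - 1L, p_value = p, n_sim = n_sim,
    detail = list(homogeneous = p > 0.05, nx = nx, ny = ny,
                  counts = counts, expected = expected)
  )
}

#' Dixon's nearest-neighbour segregation test (two types)
#'
#' Contingency test of whether points' nearest neighbours are
#' disproportionately of their own type. Counts `N_ij` (points of type i whose
#' nearest neighbour is of type j) are compared with their random-labelling
#' expectations; the overall statistic is the quadratic form in
#' `(N_AA, N_BB)` with Dixon's variance-covariance (chi-squared with 2
#' degrees of freedom for two types), and per-type statistics are the squared
#' z-scores of `N_ii`. P-values are computed both from the asymptotic
#' chi-squared distribution and by random-labelling Monte Carlo; the
#' Monte-Carlo p is authoritative.
#'
#' @param pattern A marked `point_pattern` with exactly 2 types, each with at
#'   least 5 points.
#' @param n_sim Number of random relabellings.
#' @param seed Optional integer seed.
#' @return A list with `overall` (`ppa_test`, dof 2) and `per_type` (named
#'   list of `ppa_test`, dof 1).
#' @export
nn_segregation_test <- function(pattern, n_sim = 999, seed = NULL) {
  if (!is_marked(pattern) || nlevels(pattern$taxon) != 2) {
    stop("segregation test needs exactly 2 mark types", call. = FALSE)
  }
  labs <- levels(pattern$taxon)
  n_by <- tabulate(pattern$taxon, 2)
  if (any(n_by < 5)) {
    stop("each type needs at least 5 points", call. = FALSE)
  }
  n <- n_points(pattern)
  nn <- cpp_nn(pattern$x, pattern$y)
  # structure constants of the NN graph: R reflexive pairs, Q shared NNs
  refl <- sum(nn$which[nn$which] == seq_len(n))  # 2 * (number of pairs)
  R <- refl / 2
  indeg <- tabulate(nn$which, nbins = n)
  Qk <- tabulate(indeg[indeg >= 2], nbins = max(2, max(indeg)))
  Q <- 2 * sum(choose(seq_along(Qk), 2) * Qk)
  stat_fun <- function(types) {
    nAA <- sum(types == 1 & types[nn$which] == 1)
    nBB <- sum(types == 2 & types[nn$which] == 2)
    c(nAA, nBB)
  }
  types <- as.integer(pattern$taxon)
  obs_counts <- stat_fun(types)
  moments <- dixon_moments(n_by, n, R, Q)
  dev <- obs_counts - moments$expected
  Sigma <- moments$Sigma
  C_obs <- drop(t(dev) %*% solve(Sigma) %*% dev)
  z <- dev / sqrt(diag(Sigma))
  run <- function() {
    C_sim <- numeric(n_sim)
    z2_sim <- matrix(0, n_sim, 2)
    for (s in seq_len(n_sim)) {
      perm <- sample(types)
      cnt <- stat_fun(perm)
      d <- cnt - moments$expected
      C_sim[s] <- drop(t(d) %*% solve(Sigma) %*% d)
      z2_sim[s, ] <- (d / sqrt(diag(Sigma)))^2
    }
    list(
      p_overall = (1 + sum(C_sim >= C_obs)) / (n_sim + 1),
      p_type = vapply(1:2, function(i) {
        (1 + sum(z2_sim[, i] >= z[i]^2)) / (n_sim + 1)
      }, numeric(1))
    )
  }
  mc <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  overall <- ppa_test(
    name = "nn_segregation", statistic = C_obs, dof = 2L,
    p_value = mc$p_overall, n_sim = n_sim,
    detail = list(
      counts = stats::setNames(obs_counts, paste0(labs, "->", labs)),
      expected = moments$expected,
      p_asymptotic = stats::pchisq(C_obs, 2, lower.tail = FALSE)
    )
  )
  per_type <- lapply(1:2, function(i) {
    ppa_test(
      name = paste0("nn_segregation[", labs[i], "]"),
      statistic = z[i]^2, dof = 1L, p_value = mc$p_type[i], n_sim = n_sim,
      detail = list(
        z = z[i],
        p_asymptotic = stats::pchisq(z[i]^2, 1, lower.tail = FALSE)
      )
    )
  })
  names(per_type) <- labs
  list(overall = overall, per_type = per_type)
}

# Dixon (1994) moments of (N_AA, N_BB) under random labelling, two types
dixon_moments <- function(n_by, n, R, Q) {
  p2 <- function(a) a * (a - 1) / (n * (n - 1))
  p3 <- function(a) a * (a - 1) * (a - 2) / (n * (n - 1) * (n - 2))
  p4 <- function(a) {
    a * (a - 1) * (a - 2) * (a - 3) / (n * (n - 1) * (n - 2) * (n - 3))
  }
  expected <- vapply(n_by, function(a) a * (a - 1) / (n - 1), numeric(1))
  vars <- vapply(n_by, function(a) {
    (n + R) * p2(a) + (2 * n - 2 * R + Q) * p3(a) +
      (n^2 - 3 * n - Q + R) * p4(a) - (n * p2(a))^2
  }, numeric(1))
  p22 <- n_by[1] * (n_by[1] - 1) * n_by[2] * (n_by[2] - 1) /
    (n * (n - 1) * (n - 2) * (n - 3))
  cov_ab <- (n^2 - 3 * n - Q + R) * p22 - n^2 * p2(n_by[1]) * p2(n_by[2])
  Sigma <- matrix(c(vars[1], cov_ab, cov_ab, vars[2]), 2, 2)
  list(expected = expected, Sigma = Sigma)
}

#' Kendall rank correlation between per-transect densities
#'
#' Kendall's tau-b (tie-corrected) with the p-value from [stats::cor.test()]
#' (exact for small n without ties, normal approximation otherwise). Used to
#' relate per-transect densities of two taxa across transects.
#'
#' @param x,y Equal-length numeric vectors (`n >= 3`), e.g. per-transect
#'   densities of two taxa.
#' @return A `ppa_test` with `statistic` = tau-b.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  ppa_test(
    name = "kendall", statistic = unname(ct$estimate), dof = NA_integer_,
    p_value = ct$p.value,
    detail = list(n = length(x))
  )
}
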