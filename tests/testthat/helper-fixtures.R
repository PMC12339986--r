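# Shared fixtures and independent oracles. Oracles deliberately re-derive
# quantities with naive algorithms (brute force / direct summation /
# dense sampling) so they share no code path with the implementation.

rect_10x2 <- function() window_rect(c(0, 10), c(0, 2))

# independent shoelace area
oracle_polygon_area <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + x[i] * y[j] - x[j] * y[i]
  }
  abs(s) / 2
}

# O(n^2) nearest-neighbour distances
oracle_nnd <- function(x, y) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# circumference-sampling edge-correction oracle: classify n_base equally
# spaced circle points, then refine every inside/outside transition by
# bisection so the in-window arc fraction is accurate far beyond the base
# sampling resolution
oracle_circle_fraction <- function(cx, cy, r, window, n_base = 1e6) {
  th <- seq(0, 2 * pi, length.out = n_base + 1)[-(n_base + 1)]
  px <- cx + r * cos(th)
  py <- cy + r * sin(th)
  inside <- if (window$is_rect) {
    b <- window$bbox
    px >= b["xmin"] & px <= b["xmax"] & py >= b["ymin"] & py <= b["ymax"]
  } else {
    transectppa:::cpp_in_poly(px, py, window$x, window$y)
  }
  base <- mean(inside)
  trans <- which(inside != c(inside[-1], inside[1]))
  if (length(trans) == 0) return(base)
  step <- 2 * pi / n_base
  corr <- 0
  inside_at <- function(a) {
    qx <- cx + r * cos(a)
    qy <- cy + r * sin(a)
    if (window$is_rect) {
      b <- window$bbox
      qx >= b["xmin"] && qx <= b["xmax"] && qy >= b["ymin"] && qy <= b["ymax"]
    } else {
      transectppa:::cpp_in_poly(qx, qy, window$x, window$y)
    }
  }
  for (t in trans) {
    lo <- th[t]
    hi <- th[t] + step
    state_lo <- inside[t]
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (inside_at(mid) == state_lo) lo <- mid else hi <- mid
    }
    # boundary at ~(lo+hi)/2; the base count treated the whole interval as
    # having the state of its left endpoint
    boundary <- (lo + hi) / 2
    owned <- boundary - th[t]            # true extent of state_lo in interval
    if (state_lo) {
      corr <- corr + (owned - step)      # counted step of inside, truly owned
    } else {
      corr <- corr + (step - owned)      # counted none, truly step - owned
    }
  }
  base + corr / (2 * pi)
}

# direct-summation PCF oracle: same estimator formula, naive loops
oracle_pcf <- function(pattern, r_grid, bw) {
  w <- pattern_window(pattern)
  n <- n_points(pattern)
  out <- numeric(length(r_grid))
  epan <- function(u, h) ifelse(abs(u) < h, 0.75 / h * (1 - (u / h)^2), 0)
  for (k in seq_along(r_grid)) {
    r <- r_grid[k]
    if (r == 0) {
      out[k] <- NA_real_
      next
    }
    acc <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        d <- sqrt((pattern$x[i] - pattern$x[j])^2 +
                    (pattern$y[i] - pattern$y[j])^2)
        wi <- isotropic_weight(pattern$x[i], pattern$y[i], d, w)
        acc <- acc + (epan(r - d, bw) + epan(r + d, bw)) * wi
      }
    }
    out[k] <- acc * w$area / (2 * pi * r * n * (n - 1))
  }
  out
}

# brute-force isotropic-corrected K oracle
oracle_k <- function(pattern, r_grid) {
  w <- pattern_window(pattern)
  n <- n_points(pattern)
  out <- numeric(length(r_grid))
  for (k in seq_along(r_grid)) {
    acc <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        d <- sqrt((pattern$x[i] - pattern$x[j])^2 +
                    (pattern$y[i] - pattern$y[j])^2)
        if (d <= r_grid[k]) {
          acc <- acc + isotropic_weight(pattern$x[i], pattern$y[i], d, w)
        }
      }
    }
    out[k] <- acc * w$area / (n * (n - 1))
  }
  out
}

# all-pairs Kendall concordance count (tau-a on tie-free data)
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  (conc - disc) / (n * (n - 1) / 2)
}

# small hand-made pattern used by estimator-oracle tests
toy_pattern <- function() {
  point_pattern(
    data.frame(
      x = c(1.2, 1.7, 4.5, 5.1, 8.0, 8.4),
      y = c(0.5, 1.1, 1.6, 0.4, 1.0, 1.5)
    ),
    rect_10x2()
  )
}
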