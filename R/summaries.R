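#' Pair correlation function with isotropic edge correction
#'
#' Kernel estimate of the pair correlation function g(r): the density of pairs
#' at (non-accumulative) distance r, relative to complete spatial randomness.
#' g = 1 under CSR; g > 1 indicates clustering, g < 1 overdispersion.
#'
#' The estimator is
#' `g-hat(r) = sum_{i != j} k_h(r - d_ij) w(x_i, d_ij) * |W| / (2 pi r n(n-1))`,
#' with `k_h` an Epanechnikov kernel (reflected at r = 0 so no mass leaks to
#' negative distances) and `w` Ripley's isotropic correction
#' ([isotropic_weight()]). The pair-intensity denominator uses the unbiased
#' `n(n-1)/|W|^2` convention, which matters at transect sample sizes
#' (n = 30-70). The default bandwidth is Stoyan's rule of thumb
#' `h = 0.15 / sqrt(lambda-hat)` (Epanechnikov support half-width); values at
#' distances below `h/2` are flagged unreliable.
#'
#' Estimates are never evaluated beyond half the shortest window edge (the
#' transect-scale rule, [r_max_rule()]) unless `override_scale = TRUE`.
#'
#' @param pattern A `point_pattern` with `n >= 2`.
#' @param r_max Maximum distance (m); default [r_max_rule()] of the window.
#' @param bw Epanechnikov support half-width (m); default Stoyan.
#' @param n_grid Number of equal r steps from 0 to `r_max` (grid has
#'   `n_grid + 1` points including 0).
#' @param override_scale Allow `r_max` beyond the scale rule.
#' @return A `fn_estimate`: tibble with columns `r`, `value`, `reliable`, and
#'   metadata attributes (`variant`, `bandwidth`, `correction`, ...).
#' @export
pcf <- function(pattern, r_max = NULL, bw = NULL, n_grid = 512,
                override_scale = FALSE) {
  n <- n_points(pattern)
  if (n < 2) stop("insufficient points: pcf needs n >= 2", call. = FALSE)
  w <- pattern_window(pattern)
  r_max <- check_r_max(r_max, w, override_scale)
  if (is.null(bw)) bw <- 0.15 / sqrt(n / w$area)
  pd <- pattern_pairs(pattern, r_max + bw)
  wt <- if (length(pd$d) > 0) {
    pair_weights(pattern, pd$i, pd$d) + pair_weights(pattern, pd$j, pd$d)
  } else numeric(0)
  r <- seq(0, r_max, length.out = n_grid + 1)
  s <- cpp_kernel_sum(pd$d, wt, 0, r_max / n_grid, n_grid + 1, bw, TRUE)
  value <- s * w$area / (2 * pi * r * n * (n - 1))
  value[r == 0] <- NA_real_
  fn_estimate(r, value, "pcf", bw, r_max, w, n,
              reliable = r >= bw / 2)
}

#' Inhomogeneous pair correlation function
#'
#' As [pcf()], but each pair is weighted by the reciprocal product of the
#' intensity at its two points, correcting for first-order (habitat-scale)
#' trend: `g-hat_inhom(r) = (n/(n-1)) sum_{i != j} k_h(r - d_ij) w_ij /
#' (lambda(x_i) lambda(x_j) 2 pi r |W|)`. With a constant surface
#' `lambda = n/|W|` this reduces exactly to [pcf()].
#'
#' @inheritParams pcf
#' @param intensity An `intensity_surface`, strictly positive at every data
#'   point (typically [kernel_intensity()] or a [fit_poisson()] fitted
#'   surface).
#' @return A `fn_estimate` with variant `"pcf_inhom"`.
#' @export
pcf_inhom <- function(pattern, intensity, r_max = NULL, bw = NULL,
                      n_grid = 512, override_scale = FALSE) {
  n <- n_points(pattern)
  if (n < 2) stop("insufficient points: pcf needs n >= 2", call. = FALSE)
  w <- pattern_window(pattern)
  r_max <- check_r_max(r_max, w, override_scale)
  if (is.null(bw)) bw <- 0.15 / sqrt(n / w$area)
  lam <- surface_at(intensity, pattern$x, pattern$y)
  if (any(lam <= 0)) {
    stop("intensity must be strictly positive at every data point",
         call. = FALSE)
  }
  pd <- pattern_pairs(pattern, r_max + bw)
  wt <- if (length(pd$d) > 0) {
    (pair_weights(pattern, pd$i, pd$d) + pair_weights(pattern, pd$j, pd$d)) /
      (lam[pd$i] * lam[pd$j])
  } else numeric(0)
  r <- seq(0, r_max, length.out = n_grid + 1)
  s <- cpp_kernel_sum(pd$d, wt, 0, r_max / n_grid, n_grid + 1, bw, TRUE)
  value <- (n / (n - 1)) * s / (2 * pi * r * w$area)
  value[r == 0] <- NA_real_
  fn_estimate(r, value, "pcf_inhom", bw, r_max, w, n,
              reliable = r >= bw / 2)
}

#' Multitype (cross) pair correlation function
#'
#' Cross-pair version of [pcf()] between points of two mark types; symmetric
#' in the two types by construction (each cross pair enters with the average
#' of its two endpoint edge corrections). The inhomogeneous variant is used
#' when per-type intensity surfaces are supplied.
#'
#' @inheritParams pcf
#' @param type_i,type_j Mark labels.
#' @param intensity_i,intensity_j Optional `intensity_surface`s for the two
#'   types; supply both for the inhomogeneous multitype PCF.
#' @return A `fn_estimate` with variant `"pcf_multitype"` or
#'   `"pcf_multitype_inhom"` and attribute `type_pair`.
#' @export
pcf_cross <- function(pattern, type_i, type_j, intensity_i = NULL,
                      intensity_j = NULL, r_max = NULL, bw = NULL,
                      n_grid = 512, override_scale = FALSE) {
  pi_ <- subset_taxon(pattern, type_i)
  pj_ <- subset_taxon(pattern, type_j)
  ni <- n_points(pi_)
  nj <- n_points(pj_)
  if (ni < 2 || nj < 2) {
    stop("each mark type needs >= 2 points (", type_i, ": ", ni, ", ",
         type_j, ": ", nj, ")", call. = FALSE)
  }
  w <- pattern_window(pattern)
  r_max <- check_r_max(r_max, w, override_scale)
  if (is.null(bw)) bw <- 0.15 / sqrt((ni + nj) / w$area)
  inhom <- !is.null(intensity_i) || !is.null(intensity_j)
  if (inhom && (is.null(intensity_i) || is.null(intensity_j))) {
    stop("supply both intensity surfaces for the inhomogeneous multitype PCF",
         call. = FALSE)
  }
  cp <- cpp_cross_pairs(pi_$x, pi_$y, pj_$x, pj_$y, r_max + bw)
  wt <- if (length(cp$d) > 0) {
    (pair_weights(pi_, cp$i, cp$d) + pair_weights(pj_, cp$j, cp$d)) / 2
  } else numeric(0)
  r <- seq(0, r_max, length.out = n_grid + 1)
  if (inhom) {
    li <- surface_at(intensity_i, pi_$x, pi_$y)
    lj <- surface_at(intensity_j, pj_$x, pj_$y)
    if (any(li <= 0) || any(lj <= 0)) {
      stop("intensity must be strictly positive at every data point",
           call. = FALSE)
    }
    wt <- wt / (li[cp$i] * lj[cp$j])
    s <- cpp_kernel_sum(cp$d, wt, 0, r_max / n_grid, n_grid + 1, bw, TRUE)
    value <- s / (2 * pi * r * w$area)
    variant <- "pcf_multitype_inhom"
  } else {
    s <- cpp_kernel_sum(cp$d, wt, 0, r_max / n_grid, n_grid + 1, bw, TRUE)
    value <- s * w$area / (2 * pi * r * ni * nj)
    variant <- "pcf_multitype"
  }
  value[r == 0] <- NA_real_
  out <- fn_estimate(r, value, variant, bw, r_max, w, ni + nj,
                     reliable = r >= bw / 2)
  attr(out, "type_pair") <- c(type_i, type_j)
  out
}

#' Ripley's K and the L function
#'
#' Isotropic-corrected empirical K function (accumulative weighted pair
#' counts) and its variance-stabilised transform `L(r) = sqrt(K(r)/pi)`;
#' under CSR `E[L(r)] = r`. With an `intensity` surface the inhomogeneous
#' versions are computed. The L function is the summary used by the DCLF
#' goodness-of-fit test.
#'
#' @inheritParams pcf
#' @param intensity Optional `intensity_surface` for the inhomogeneous K.
#' @param n_grid Number of equal r steps.
#' @return A `fn_estimate` with variant `"K"` (or `"L"`).
#' @export
k_function <- function(pattern, r_max = NULL, intensity = NULL, n_grid = 512,
                       override_scale = FALSE) {
  n <- n_points(pattern)
  if (n < 2) stop("insufficient points: K needs n >= 2", call. = FALSE)
  w <- pattern_window(pattern)
  r_max <- check_r_max(r_max, w, override_scale)
  pd <- pattern_pairs(pattern, r_max)
  r <- seq(0, r_max, length.out = n_grid + 1)
  if (length(pd$d) == 0) {
    value <- rep(0, length(r))
  } else {
    wt <- pair_weights(pattern, pd$i, pd$d) + pair_weights(pattern, pd$j, pd$d)
    if (!is.null(intensity)) {
      lam <- surface_at(intensity, pattern$x, pattern$y)
      if (any(lam <= 0)) {
        stop("intensity must be strictly positive at every data point",
             call. = FALSE)
      }
      wt <- wt / (lam[pd$i] * lam[pd$j])
      scale <- (n / (n - 1)) / w$area
    } else {
      scale <- w$area / (n * (n - 1))
    }
    ord <- order(pd$d)
    cs <- cumsum(wt[ord])
    idx <- findInterval(r, pd$d[ord])
    value <- c(0, cs)[idx + 1] * scale
  }
  fn_estimate(r, value, if (is.null(intensity)) "K" else "K_inhom",
              NA_real_, r_max, w, n, reliable = rep(TRUE, length(r)))
}

#' @rdname k_function
#' @export
l_function <- function(pattern, r_max = NULL, intensity = NULL, n_grid = 512,
                       override_scale = FALSE) {
  k <- k_function(pattern, r_max, intensity, n_grid, override_scale)
  out <- fn_estimate(k$r, sqrt(k$value / pi), "L", NA_real_,
                     attr(k, "r_max"), attr(k, "window"), attr(k, "n"),
                     reliable = k$reliable)
  out
}

#' Cross-type K and L functions
#'
#' Accumulative cross-pair counts between two mark types, used as the summary
#' statistic for bivariate goodness-of-fit testing.
#'
#' @inheritParams pcf_cross
#' @return A `fn_estimate` with variant `"K_cross"` / `"L_cross"`.
#' @export
k_cross <- function(pattern, type_i, type_j, r_max = NULL, n_grid = 512,
                    override_scale = FALSE) {
  pi_ <- subset_taxon(pattern, type_i)
  pj_ <- subset_taxon(pattern, type_j)
  ni <- n_points(pi_)
  nj <- n_points(pj_)
  if (ni < 1 || nj < 1) stop("both mark types must be present", call. = FALSE)
  w <- pattern_window(pattern)
  r_max <- check_r_max(r_max, w, override_scale)
  cp <- cpp_cross_pairs(pi_$x, pi_$y, pj_$x, pj_$y, r_max)
  r <- seq(0, r_max, length.out = n_grid + 1)
  if (length(cp$d) == 0) {
    value <- rep(0, length(r))
  } else {
    wt <- (pair_weights(pi_, cp$i, cp$d) + pair_weights(pj_, cp$j, cp$d)) / 2
    ord <- order(cp$d)
    cs <- cumsum(wt[ord])
    idx <- findInterval(r, cp$d[ord])
    value <- c(0, cs)[idx + 1] * w$area / (ni * nj)
  }
  out <- fn_estimate(r, value, "K_cross", NA_real_, r_max, w, ni + nj,
                     reliable = rep(TRUE, length(r)))
  attr(out, "type_pair") <- c(type_i, type_j)
  out
}

#' @rdname k_cross
#' @export
l_cross <- function(pattern, type_i, type_j, r_max = NULL, n_grid = 512,
                    override_scale = FALSE) {
  k <- k_cross(pattern, type_i, type_j, r_max, n_grid, override_scale)
  out <- fn_estimate(k$r, sqrt(k$value / pi), "L_cross", NA_real_,
                     attr(k, "r_max"), attr(k, "window"), attr(k, "n"),
                     reliable = k$reliable)
  attr(out, "type_pair") <- attr(k, "type_pair")
  out
}

# ---- shared helpers ----

check_r_max <- function(r_max, window, override_scale) {
  rule <- r_max_rule(window)
  if (is.null(r_max)) return(rule)
  if (r_max > rule + 1e-12 && !override_scale) {
    stop(sprintf(
      "r_max = %.3g m exceeds half the shortest window edge (%.3g m); %s",
      r_max, rule, "set override_scale = TRUE to force"), call. = FALSE)
  }
  r_max
}

pattern_pairs <- function(pattern, rmax) {
  cpp_close_pairs(pattern$x, pattern$y, rmax)
}

fn_estimate <- function(r, value, variant, bandwidth, r_max, window, n,
                        reliable) {
  out <- tibble::new_tibble(
    list(r = r, value = value, reliable = reliable),
    nrow = length(r)
  )
  structure(
    out,
    variant = variant, bandwidth = bandwidth, correction = "isotropic",
    r_max = r_max, window = window, n = n,
    class = c("fn_estimate", class(out))
  )
}

#' @export
print.fn_estimate <- function(x, ...) {
  cat(sprintf("<fn_estimate> %s, isotropic correction, r in [0, %.3g] m%s\n",
              attr(x, "variant"), attr(x, "r_max"),
              if (!is.na(attr(x, "bandwidth"))) {
                sprintf(", kernel bw %.3g m", attr(x, "bandwidth"))
              } else ""))
  NextMethod()
}
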