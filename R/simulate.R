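#' Simulate complete spatial randomness (CSR)
#'
#' Either conditional on a fixed number of points (`n`) or with a Poisson
#' number of points at a given `intensity` (ind m^-2). Points are uniform on
#' the window (rejection-sampled from the bounding box for polygonal windows).
#'
#' @param window A [window_polygon()] object.
#' @param n Exact number of points (conditional simulation).
#' @param intensity Intensity for the unconditional (Poisson count) variant;
#'   exactly one of `n` and `intensity` must be given.
#' @param seed Optional integer seed; the same seed reproduces the pattern.
#' @return A `point_pattern`.
#' @export
simulate_csr <- function(window, n = NULL, intensity = NULL, seed = NULL) {
  if (is.null(n) == is.null(intensity)) {
    stop("give exactly one of `n` or `intensity`", call. = FALSE)
  }
  run <- function() {
    m <- if (is.null(n)) stats::rpois(1, intensity * window$area) else n
    xy <- runif_window(window, m)
    new_pattern(xy$x, xy$y, window)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

runif_window <- function(window, n) {
  b <- window$bbox
  if (n == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  if (window$is_rect) {
    return(data.frame(
      x = stats::runif(n, b["xmin"], b["xmax"]),
      y = stats::runif(n, b["ymin"], b["ymax"])
    ))
  }
  out_x <- numeric(0)
  out_y <- numeric(0)
  while (length(out_x) < n) {
    m <- ceiling((n - length(out_x)) *
                   (b["xmax"] - b["xmin"]) * (b["ymax"] - b["ymin"]) /
                   window$area * 1.2) + 5
    x <- stats::runif(m, b["xmin"], b["xmax"])
    y <- stats::runif(m, b["ymin"], b["ymax"])
    keep <- cpp_in_poly(x, y, window$x, window$y)
    out_x <- c(out_x, x[keep])
    out_y <- c(out_y, y[keep])
  }
  data.frame(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

#' Simulate a Thomas cluster process
#'
#' Poisson parents of intensity `kappa` on the window dilated by `4 * sigma`
#' (so clusters straddling the boundary are represented), each with a
#' Poisson(`mu`) number of offspring displaced by an isotropic Gaussian of
#' standard deviation `sigma`; offspring outside the window are discarded.
#' The retained intensity is approximately `kappa * mu`. A dispersal-limited
#' recruitment model for sessile fauna.
#'
#' @param kappa Parent intensity (m^-2), `> 0`.
#' @param sigma Offspring dispersal standard deviation (m), `> 0`.
#' @param mu Mean offspring per parent, `> 0`.
#' @param window A [window_polygon()] object.
#' @param trend Optional `intensity_surface`: offspring are independently
#'   thinned with probability proportional to the surface (max-normalised),
#'   giving the inhomogeneous Thomas process.
#' @param seed Optional integer seed.
#' @return A `point_pattern`.
#' @export
simulate_thomas <- function(kappa, sigma, mu, window, trend = NULL,
                            seed = NULL) {
  stopifnot(kappa > 0, sigma > 0, mu > 0)
  run <- function() {
    b <- window$bbox
    dx <- 4 * sigma
    lx <- (b["xmax"] - b["xmin"]) + 2 * dx
    ly <- (b["ymax"] - b["ymin"]) + 2 * dx
    n_par <- stats::rpois(1, kappa * lx * ly)
    if (n_par == 0) {
      return(new_pattern(numeric(0), numeric(0), window))
    }
    px <- stats::runif(n_par, b["xmin"] - dx, b["xmax"] + dx)
    py <- stats::runif(n_par, b["ymin"] - dx, b["ymax"] + dx)
    n_off <- stats::rpois(n_par, mu)
    x <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, sigma)
    y <- rep(py, n_off) + stats::rnorm(sum(n_off), 0, sigma)
    keep <- points_in_window(window, x, y)
    x <- x[keep]
    y <- y[keep]
    if (!is.null(trend) && length(x) > 0) {
      p <- surface_at(trend, x, y)
      p <- p / max(trend$value)
      keep2 <- stats::runif(length(x)) < p
      x <- x[keep2]
      y <- y[keep2]
    }
    new_pattern(x, y, window)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a linked Thomas process (shared parents, two types)
#'
#' Both types share one Poisson parent process (intensity `kappa`) and the
#' same dispersal `sigma`; each parent generates Poisson(`mu_i`) offspring of
#' each type independently. The shared parents induce cross-type clustering -
#' the facilitation model of the driver ladder.
#'
#' @inheritParams simulate_thomas
#' @param mu_by_type Named numeric vector of length 2: mean offspring per
#'   parent for each type; names become the mark labels.
#' @return A marked `point_pattern` with two mark levels.
#' @export
simulate_linked_thomas <- function(kappa, sigma, mu_by_type, window,
                                   seed = NULL) {
  stopifnot(kappa > 0, sigma > 0, length(mu_by_type) == 2,
            !is.null(names(mu_by_type)))
  run <- function() {
    b <- window$bbox
    dx <- 4 * sigma
    lx <- (b["xmax"] - b["xmin"]) + 2 * dx
    ly <- (b["ymax"] - b["ymin"]) + 2 * dx
    n_par <- stats::rpois(1, kappa * lx * ly)
    px <- stats::runif(n_par, b["xmin"] - dx, b["xmax"] + dx)
    py <- stats::runif(n_par, b["ymin"] - dx, b["ymax"] + dx)
    dfs <- lapply(names(mu_by_type), function(lab) {
      if (n_par == 0) {
        return(data.frame(x = numeric(0), y = numeric(0), taxon = character(0)))
      }
      n_off <- stats::rpois(n_par, mu_by_type[[lab]])
      x <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, sigma)
      y <- rep(py, n_off) + stats::rnorm(sum(n_off), 0, sigma)
      keep <- points_in_window(window, x, y)
      data.frame(x = x[keep], y = y[keep],
                 taxon = rep(lab, sum(keep)))
    })
    df <- do.call(rbind, dfs)
    new_pattern(df$x, df$y, window, taxon = df$taxon,
                levels = names(mu_by_type))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a pairwise-interaction Gibbs process (hard core / soft core)
#'
#' Conditional (fixed-n) simulation by a long Metropolis shift chain: at each
#' step one point is proposed a uniform relocation, accepted with the
#' interaction (and optional log-linear trend) density ratio. The hard-core
#' process forbids pairs closer than `hc_radius`; the soft-core process
#' penalises close pairs through `h(d) = exp(-(sc_sigma/d)^(2/sc_kappa))`
#' with `sc_kappa` in `[0.1, 0.9]` (small values approach a hard core).
#' Inhibition models competition between organisms.
#'
#' @param window A [window_polygon()] object.
#' @param n Number of points.
#' @param family `"hardcore"` or `"softcore"`.
#' @param hc_radius Hard-core distance (m), required for `"hardcore"`.
#' @param sc_sigma,sc_kappa Soft-core scale (m) and exponent parameter.
#' @param trend_coefs Optional named vector (`x`, `y`) of log-linear trend
#'   coefficients.
#' @param n_sweeps Number of Metropolis proposals (default 1e5).
#' @param seed Optional integer seed.
#' @return A `point_pattern`.
#' @export
simulate_gibbs <- function(window, n, family = c("hardcore", "softcore"),
                           hc_radius = NULL, sc_sigma = NULL, sc_kappa = NULL,
                           trend_coefs = NULL, n_sweeps = 1e5, seed = NULL) {
  family <- match.arg(family)
  if (family == "hardcore") {
    stopifnot(!is.null(hc_radius), hc_radius > 0)
    # crude packing feasibility: disks of radius hc/2 must fit in |W|
    if (n * pi * (hc_radius / 2)^2 > window$area) {
      stop("infeasible packing: ", n, " hard-core disks of radius ",
           hc_radius / 2, " m exceed the window area", call. = FALSE)
    }
  } else {
    stopifnot(!is.null(sc_sigma), sc_sigma >= 0, !is.null(sc_kappa))
    if (sc_kappa < 0.1 || sc_kappa > 0.9) {
      stop("sc_kappa must be within [0.1, 0.9]", call. = FALSE)
    }
  }
  bx <- if (!is.null(trend_coefs) && "x" %in% names(trend_coefs)) {
    unname(trend_coefs["x"])
  } else 0
  by <- if (!is.null(trend_coefs) && "y" %in% names(trend_coefs)) {
    unname(trend_coefs["y"])
  } else 0
  run <- function() {
    init <- if (family == "hardcore") {
      dart_throw(window, n, hc_radius)
    } else {
      runif_window(window, n)
    }
    st <- cpp_gibbs_chain(init$x, init$y, window$x, window$y,
                          ifelse(family == "hardcore", 0L, 1L),
                          hc_radius %||% 0, sc_sigma %||% 0,
                          sc_kappa %||% 0.5, bx, by, as.integer(n_sweeps))
    new_pattern(st$x, st$y, window)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# sequential inhibition starting state for the hard-core chain
dart_throw <- function(window, n, hc) {
  x <- numeric(0)
  y <- numeric(0)
  tries <- 0
  max_tries <- 2000 * n
  while (length(x) < n) {
    p <- runif_window(window, 1)
    tries <- tries + 1
    if (tries > max_tries) {
      stop("infeasible packing: could not place ", n,
           " points at hard-core distance ", hc, call. = FALSE)
    }
    if (length(x) == 0 || min((x - p$x)^2 + (y - p$y)^2) >= hc^2) {
      x <- c(x, p$x)
      y <- c(y, p$y)
    }
  }
  data.frame(x = x, y = y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
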