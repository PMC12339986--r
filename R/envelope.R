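#' CSR reference model for envelopes and goodness-of-fit
#'
#' A lightweight model object representing complete spatial randomness
#' conditional on the observed number of points (and, for marked patterns,
#' independent CSR per type with the observed counts).
#'
#' @param pattern A `point_pattern`.
#' @return A `csr_model`; supports [stats::simulate()].
#' @export
csr_model <- function(pattern) {
  structure(
    list(
      family = "csr",
      window = pattern_window(pattern),
      n = n_points(pattern),
      counts = if (is_marked(pattern)) table(pattern$taxon) else NULL,
      levels = mark_levels(pattern),
      flagged = FALSE
    ),
    class = "csr_model"
  )
}

#' @export
print.csr_model <- function(x, ...) {
  cat(sprintf("<csr_model> conditional on n = %d\n", x$n))
  invisible(x)
}

#' @export
simulate.csr_model <- function(object, nsim = 1, seed = NULL, ...) {
  run <- function() {
    if (is.null(object$counts)) {
      simulate_csr(object$window, n = object$n)
    } else {
      dfs <- lapply(names(object$counts), function(lab) {
        xy <- runif_window(object$window, object$counts[[lab]])
        xy$taxon <- rep(lab, nrow(xy))
        xy
      })
      df <- do.call(rbind, dfs)
      new_pattern(df$x, df$y, object$window, taxon = df$taxon,
                  levels = object$levels)
    }
  }
  simulate_wrapper(run, nsim, seed)
}

#' Monte-Carlo simulation envelope for a summary function
#'
#' Simulates `n_sim` replicates from a model, evaluates the summary statistic
#' on each, and takes the `rank`-th largest and smallest simulated values at
#' each distance as the envelope limits (999 simulations and the 49th
#' extremes by default, a pointwise two-sided test at level
#' `2 rank / (n_sim + 1) = 0.098`). Maximal intervals where the observed
#' statistic leaves the envelope are extracted as excursions: `above`
#' indicates clustering (PCF > envelope), `below` overdispersion.
#'
#' When `n_sim` differs from 999 and `rank` is not given, the rank is scaled
#' as `floor(49 (n_sim + 1) / 1000)` to preserve the nominal level.
#'
#' @param pattern A `point_pattern` (the observed data).
#' @param statistic A function `pattern -> fn_estimate`, evaluated on the data
#'   and on every simulation; must return values on a fixed r grid.
#' @param model A model object with a [stats::simulate()] method
#'   ([csr_model()], `poisson_fit`, `thomas_fit`, `gibbs_fit`, ...).
#' @param n_sim Number of simulations.
#' @param rank Envelope order statistic.
#' @param seed Optional integer seed.
#' @return An `envelope_result`: tibble `r`, `obs`, `lo`, `hi`, `reliable`
#'   with attributes `excursions` (tibble `r_start`, `r_end`, `direction`,
#'   `weak`), `n_sim`, `rank`, `model_family`.
#' @export
envelope <- function(pattern, statistic, model = csr_model(pattern),
                     n_sim = 999, rank = NULL, seed = NULL) {
  if (is.null(rank)) rank <- scaled_envelope_rank(n_sim)
  stopifnot(rank >= 1, rank <= n_sim / 2)
  run <- function() {
    obs <- statistic(pattern)
    r <- obs$r
    sims <- matrix(NA_real_, nrow = length(r), ncol = n_sim)
    fails <- 0
    for (s in seq_len(n_sim)) {
      sim_pat <- tryCatch(stats::simulate(model), error = function(e) NULL)
      est <- if (is.null(sim_pat)) NULL else {
        tryCatch(statistic(sim_pat), error = function(e) NULL)
      }
      if (is.null(est)) {
        fails <- fails + 1
        if (fails > max(1, 0.01 * n_sim)) {
          stop("simulation failure in more than 1% of envelope replicates",
               call. = FALSE)
        }
        next
      }
      sims[, s] <- est$value
    }
    sims <- sims[, colSums(is.na(sims)) < nrow(sims), drop = FALSE]
    m <- ncol(sims)
    lo <- numeric(nrow(sims))
    hi <- numeric(nrow(sims))
    for (i in seq_len(nrow(sims))) {
      v <- sims[i, ]
      v <- v[!is.na(v)]
      if (length(v) < 2 * rank) {
        lo[i] <- NA_real_
        hi[i] <- NA_real_
      } else {
        v <- sort.int(v, partial = c(rank, length(v) - rank + 1))
        lo[i] <- v[rank]
        hi[i] <- v[length(v) - rank + 1]
      }
    }
    obs_value <- obs$value
    obs_reliable <- obs$reliable
    out <- structure(
      tibble::tibble(r = r, obs = obs_value, lo = lo, hi = hi,
                     reliable = obs_reliable),
      n_sim = ncol(sims), rank = rank,
      model_family = model$family %||% "custom",
      variant = attr(obs, "variant"),
      bandwidth = attr(obs, "bandwidth"),
      window = pattern_window(pattern),
      class = c("envelope_result", "tbl_df", "tbl", "data.frame")
    )
    attr(out, "excursions") <- extract_excursions(out)
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @keywords internal
scaled_envelope_rank <- function(n_sim) {
  max(1L, as.integer(floor(49 * (n_sim + 1) / 1000)))
}

# maximal runs where the observed statistic leaves [lo, hi]; single-grid-step
# grazes are kept but flagged weak
extract_excursions <- function(env) {
  ok <- env$reliable & is.finite(env$obs) & is.finite(env$lo) &
    is.finite(env$hi)
  state <- rep(0L, nrow(env))
  state[ok & env$obs > env$hi] <- 1L
  state[ok & env$obs < env$lo] <- -1L
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values != 0L
  if (!any(keep)) {
    return(tibble::tibble(r_start = numeric(0), r_end = numeric(0),
                          direction = character(0), weak = logical(0)))
  }
  tibble::tibble(
    r_start = env$r[starts[keep]],
    r_end = env$r[ends[keep]],
    direction = ifelse(runs$values[keep] > 0, "above", "below"),
    weak = runs$lengths[keep] <= 1
  )
}

#' @export
print.envelope_result <- function(x, ...) {
  exc <- attr(x, "excursions")
  cat(sprintf("<envelope_result> %s vs %s, %d simulations, rank %d\n",
              attr(x, "variant"), attr(x, "model_family"),
              attr(x, "n_sim"), attr(x, "rank")))
  if (nrow(exc) == 0) {
    cat("no departure from the envelope\n")
  } else {
    for (i in seq_len(nrow(exc))) {
      cat(sprintf("  %s excursion on [%.3g, %.3g] m%s\n", exc$direction[i],
                  exc$r_start[i], exc$r_end[i],
                  if (exc$weak[i]) " (single grid point)" else ""))
    }
  }
  invisible(x)
}

#' Diggle's (DCLF) goodness-of-fit test
#'
#' Monte-Carlo test of a fitted point-process model from the integrated
#' squared deviation of a summary function (the L function by default):
#' `u = integral_0^rmax (Lhat(r) - Lbar(r))^2 dr`, where `Lbar` is the mean of
#' the other curves (observed and simulated curves are treated exchangeably,
#' each compared to the mean of the remaining simulations). The p-value
#' `p_d = (1 + #{u_sim >= u_obs}) / (n_sim + 1)` is read as evidence of fit:
#' the closer to 1, the better the model reproduces the observed pattern.
#'
#' @param pattern A `point_pattern`.
#' @param model A model object with a [stats::simulate()] method.
#' @param r_max Upper integration limit (m); default [r_max_rule()].
#' @param n_sim Number of model simulations.
#' @param statistic A function `pattern -> fn_estimate`; default the
#'   isotropic-corrected [l_function()].
#' @param n_grid r-grid steps for the statistic.
#' @param seed Optional integer seed.
#' @return A `ppa_test` with `statistic` (u_obs), `p_value` (p_d), `n_sim`.
#' @export
dclf_test <- function(pattern, model = csr_model(pattern), r_max = NULL,
                      n_sim = 999, statistic = NULL, n_grid = 128,
                      seed = NULL) {
  w <- pattern_window(pattern)
  r_max <- check_r_max(r_max, w, FALSE)
  if (is.null(statistic)) {
    statistic <- function(p) l_function(p, r_max = r_max, n_grid = n_grid)
  }
  run <- function() {
    obs <- statistic(pattern)
    r <- obs$r
    dr <- r[2] - r[1]
    curves <- matrix(NA_real_, nrow = length(r), ncol = n_sim)
    fails <- 0
    for (s in seq_len(n_sim)) {
      est <- tryCatch(statistic(stats::simulate(model)),
                      error = function(e) NULL)
      if (is.null(est)) {
        fails <- fails + 1
        if (fails > max(1, 0.01 * n_sim)) {
          stop("simulation failure in more than 1% of DCLF replicates",
               call. = FALSE)
        }
        next
      }
      curves[, s] <- est$value
    }
    curves <- curves[, colSums(is.na(curves)) < nrow(curves), drop = FALSE]
    m <- ncol(curves)
    total <- rowSums(curves)
    trapz_w <- rep(dr, length(r))
    trapz_w[c(1, length(r))] <- dr / 2
    u_obs <- sum(trapz_w * (obs$value - total / m)^2)
    u_sim <- vapply(seq_len(m), function(s) {
      ref <- (total - curves[, s]) / (m - 1)
      sum(trapz_w * (curves[, s] - ref)^2)
    }, numeric(1))
    p <- (1 + sum(u_sim >= u_obs)) / (m + 1)
    ppa_test(
      name = "dclf",
      statistic = u_obs, dof = NA_integer_, p_value = p, n_sim = m,
      detail = list(model_family = model$family %||% "custom", r_max = r_max)
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# shared container for test results
ppa_test <- function(name, statistic, dof, p_value, n_sim = NA_integer_,
                     detail = list()) {
  structure(
    list(name = name, statistic = statistic, dof = dof, p_value = p_value,
         n_sim = n_sim, verdict_threshold = 0.05, detail = detail),
    class = "ppa_test"
  )
}

#' @export
print.ppa_test <- function(x, ...) {
  cat(sprintf("<ppa_test> %s: statistic = %.4g%s, p = %.4g%s\n",
              x$name, x$statistic,
              if (!is.na(x$dof)) sprintf(" (dof %d)", x$dof) else "",
              x$p_value,
              if (!is.na(x$n_sim)) sprintf(" (%d simulations)", x$n_sim)
              else ""))
  invisible(x)
}
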