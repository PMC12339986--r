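#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns per-term (or per-point / per-r)
#' rows, `glance()` a one-row model summary.
#'
#' @param x A fitted model or test object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.poisson_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.poisson_fit <- function(x, ...) {
  tibble::tibble(family = x$family, trend = x$trend, logLik = x$logLik,
                 AIC = x$aic, df = x$k, nobs = x$n)
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.thomas_fit <- function(x, ...) {
  tibble::tibble(term = c("kappa", "sigma", "mu"),
                 estimate = c(x$kappa, x$sigma, x$mu))
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.thomas_fit <- function(x, ...) {
  tibble::tibble(family = x$family, contrast = x$contrast,
                 flagged = x$flagged, nobs = x$n)
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.linked_thomas_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kappa", "sigma", paste0("mu[", names(x$mu_by_type), "]")),
    estimate = c(x$kappa, x$sigma, unname(x$mu_by_type))
  )
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.linked_thomas_fit <- function(x, ...) {
  tibble::tibble(family = x$family, contrast = x$contrast,
                 flagged = x$flagged, nobs = x$n)
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.gibbs_fit <- function(x, ...) {
  terms <- c(names(x$beta),
             if (x$family == "hardcore") "hc_radius" else c("sc_sigma", "sc_kappa"))
  est <- c(unname(x$beta),
           if (x$family == "hardcore") x$hc_radius else c(x$sc_sigma, x$sc_kappa))
  tibble::tibble(term = terms, estimate = est)
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.gibbs_fit <- function(x, ...) {
  tibble::tibble(family = x$family, trend = x$trend, logPL = x$logPL,
                 pseudo_AIC = x$pseudo_aic, flagged = x$flagged, nobs = x$n)
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.ppa_test <- function(x, ...) {
  tibble::tibble(name = x$name, statistic = x$statistic, dof = x$dof,
                 p_value = x$p_value, n_sim = x$n_sim)
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.ppa_test <- tidy.ppa_test

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.nnd_summary <- function(x, ...) {
  tibble::tibble(point = seq_len(x$n), nn = x$which, distance = x$distances)
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.nnd_summary <- function(x, ...) {
  tibble::tibble(n = x$n, nnd_min = x$min, nnd_mean = x$mean)
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.envelope_result <- function(x, ...) {
  attr(x, "excursions")
}

#' Summarise a transect report as a tibble
#'
#' One row per analysed taxon plus one for the bivariate analysis: sample
#' size, density, homogeneity, classification and driver verdict.
#'
#' @param x A `transect_report`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.transect_report <- function(x, ...) {
  rows <- purrr::map_dfr(x$univariate, function(u) {
    if (!is.null(u$status) && u$status == "excluded") {
      tibble::tibble(scope = "univariate", taxon = u$taxon, n = u$n,
                     status = "excluded", label = NA_character_,
                     homogeneous = NA, driver = NA_character_,
                     p_d = NA_real_, note = u$reason)
    } else {
      tibble::tibble(
        scope = "univariate", taxon = u$taxon, n = u$n, status = "analysed",
        label = u$classification$label,
        homogeneous = u$classification$homogeneous,
        driver = u$verdict$driver,
        p_d = u$verdict$p_d %||% NA_real_,
        note = u$verdict$evidence_notes
      )
    }
  })
  if (!is.null(x$bivariate)) {
    b <- x$bivariate
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      scope = "bivariate", taxon = paste(b$taxa, collapse = "+"),
      n = NA_integer_, status = "analysed",
      label = b$classification$label,
      homogeneous = b$classification$homogeneous,
      driver = b$verdict$driver,
      p_d = b$verdict$p_d %||% NA_real_,
      note = b$verdict$evidence_notes
    ))
  }
  rows
}
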