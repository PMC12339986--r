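#' Analysis configuration
#'
#' Bundles every tunable of the transect pipeline, defaulting to the study
#' settings: 999 Monte-Carlo simulations with 49th-extreme envelope limits,
#' 1 m kernel-intensity bandwidth, 3 x 2 quadrats, the half-shortest-edge
#' `r_max` rule, soft-core `sc_kappa` profiled over 0.1-0.9, and the 30-point
#' minimum per taxon. Every value is echoed into reports.
#'
#' `n_sim_envelope`, `n_sim_gof` and `n_sim_quadrat` may be lowered for
#' large simulation studies; when the envelope rank is left `NULL` it is
#' rescaled as `floor(49 (n_sim + 1) / 1000)` to preserve the nominal
#' pointwise level of about 0.098.
#'
#' @param n_sim Default simulation count for all three Monte-Carlo stages.
#' @param n_sim_envelope,n_sim_gof,n_sim_quadrat Stage-specific overrides.
#' @param envelope_rank Envelope order statistic (`NULL` = scaled rule).
#' @param bandwidth_intensity Kernel intensity bandwidth (m).
#' @param grid_resolution Intensity/quadrature grid (m).
#' @param quadrats `c(nx, ny)` quadrat layout.
#' @param r_max Maximum analysis distance (m); `NULL` = half shortest edge.
#' @param sc_kappa_grid Soft-core exponent grid.
#' @param dummy_spacing Berman-Turner dummy spacing (m).
#' @param min_points Minimum points per taxon for SPPA.
#' @param tie_band `p_d` near-tie width giving indeterminate verdicts.
#' @param top_per_family Shortlist size per model family.
#' @param pcf_n_grid,gof_n_grid r-grid steps for envelopes / GOF statistics.
#' @param seed Optional integer seed making the whole analysis deterministic.
#' @return A `ppa_config` list.
#' @export
sppa_config <- function(n_sim = 999,
                        n_sim_envelope = n_sim,
                        n_sim_gof = n_sim,
                        n_sim_quadrat = n_sim,
                        envelope_rank = NULL,
                        bandwidth_intensity = 1,
                        grid_resolution = 0.05,
                        quadrats = c(3, 2),
                        r_max = NULL,
                        sc_kappa_grid = seq(0.1, 0.9, by = 0.1),
                        dummy_spacing = 0.1,
                        min_points = 30,
                        tie_band = 0.05,
                        top_per_family = 2,
                        pcf_n_grid = 256,
                        gof_n_grid = 128,
                        seed = NULL) {
  structure(
    list(
      n_sim = n_sim, n_sim_envelope = n_sim_envelope, n_sim_gof = n_sim_gof,
      n_sim_quadrat = n_sim_quadrat, envelope_rank = envelope_rank,
      bandwidth_intensity = bandwidth_intensity,
      grid_resolution = grid_resolution, quadrats = quadrats, r_max = r_max,
      sc_kappa_grid = sc_kappa_grid, dummy_spacing = dummy_spacing,
      min_points = min_points, tie_band = tie_band,
      top_per_family = top_per_family, pcf_n_grid = pcf_n_grid,
      gof_n_grid = gof_n_grid, seed = seed
    ),
    class = "ppa_config"
  )
}

#' Read a point pattern from CSV with a window file
#'
#' The CSV must have numeric columns `x` and `y` (metres) and may have
#' `taxon`; the window is a WKT `POLYGON` or GeoJSON `Polygon` file. Rows
#' outside the window are an error naming the offending row numbers.
#'
#' @param path CSV path.
#' @param window_path Path to a `.wkt` or `.geojson`/`.json` window file, or
#'   a `ppa_window` object.
#' @return A `point_pattern`.
#' @export
read_pattern_csv <- function(path, window_path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty pattern file: ", path, call. = FALSE)
  for (col in c("x", "y")) {
    if (!col %in% names(df)) {
      stop("missing column `", col, "` in ", path, call. = FALSE)
    }
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
      stop("non-numeric `", col, "` values in rows: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  w <- if (inherits(window_path, "ppa_window")) {
    window_path
  } else {
    read_window(window_path)
  }
  cols <- intersect(c("x", "y", "taxon"), names(df))
  point_pattern(df[, cols, drop = FALSE], w)
}

#' @rdname read_pattern_csv
#' @param pattern A `point_pattern` to write.
#' @export
write_pattern_csv <- function(pattern, path) {
  df <- as.data.frame(pattern)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Window serialisation: WKT and GeoJSON
#'
#' `read_window()` dispatches on the file extension (`.wkt` vs
#' `.geojson`/`.json`); writers emit single-ring polygons.
#'
#' @param path File path.
#' @return A `ppa_window` (readers) or the path invisibly (writers).
#' @export
read_window <- function(path) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    window_from_geojson(paste(readLines(path, warn = FALSE), collapse = "\n"))
  } else {
    window_from_wkt(paste(readLines(path, warn = FALSE), collapse = " "))
  }
}

#' @rdname read_window
#' @param text WKT `POLYGON ((x y, ...))` text (no holes).
#' @export
window_from_wkt <- function(text) {
  m <- regmatches(text, regexpr("POLYGON\\s*\\(\\(([^)]*)\\)\\)", text,
                                ignore.case = TRUE))
  if (length(m) == 0) stop("not a WKT POLYGON: ", text, call. = FALSE)
  inner <- sub(".*\\(\\(", "", sub("\\)\\).*", "", m))
  parts <- strsplit(trimws(strsplit(inner, ",")[[1]]), "\\s+")
  xy <- do.call(rbind, lapply(parts, as.numeric))
  window_polygon(data.frame(x = xy[, 1], y = xy[, 2]))
}

#' @rdname read_window
#' @export
window_from_geojson <- function(text) {
  gj <- jsonlite::fromJSON(text, simplifyMatrix = TRUE)
  geom <- if (!is.null(gj$type) && gj$type == "Polygon") gj else gj$geometry
  if (is.null(geom) || geom$type != "Polygon") {
    stop("not a GeoJSON Polygon", call. = FALSE)
  }
  ring <- if (is.list(geom$coordinates)) geom$coordinates[[1]] else
    geom$coordinates[1, , ]
  window_polygon(data.frame(x = ring[, 1], y = ring[, 2]))
}

#' @rdname read_window
#' @param window A `ppa_window`.
#' @export
window_to_wkt <- function(window) {
  ring <- sprintf("%.10g %.10g", c(window$x, window$x[1]),
                  c(window$y, window$y[1]))
  paste0("POLYGON ((", paste(ring, collapse = ", "), "))")
}

#' @rdname read_window
#' @export
write_window_wkt <- function(window, path) {
  writeLines(window_to_wkt(window), path)
  invisible(path)
}

#' Write a summary-function estimate (or envelope) to CSV with JSON metadata
#'
#' The CSV holds `r`, `value` (plus `lo`, `hi` for envelopes); the metadata
#' sidecar `<path>.json` records the variant, correction, bandwidth and grid.
#'
#' @param est A `fn_estimate` or `envelope_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fn_estimate <- function(est, path) {
  utils::write.csv(as.data.frame(est), path, row.names = FALSE)
  meta <- list(
    variant = attr(est, "variant"),
    correction = attr(est, "correction") %||% "isotropic",
    smoothing_bandwidth = attr(est, "bandwidth"),
    r_max = attr(est, "r_max"),
    n = attr(est, "n"),
    n_sim = attr(est, "n_sim"),
    rank = attr(est, "rank")
  )
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialise a fitted model to JSON
#'
#' Writes the family, parameter estimates, and fit criterion of any fitted
#' model object (`poisson_fit`, `thomas_fit`, `linked_thomas_fit`,
#' `gibbs_fit`) as a small JSON record.
#'
#' @param fit A fitted model object with `tidy()`/`glance()` methods.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(fit, path) {
  rec <- list(
    summary = as.list(generics::glance(fit)),
    parameters = stats::setNames(
      as.list(generics::tidy(fit)$estimate),
      generics::tidy(fit)$term
    ),
    provenance = fit$provenance %||% NA_character_
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a transect report to disk
#'
#' Emits the machine-readable summary (`report.json`) and a human-readable
#' Markdown digest (`report.md`) of a [run_transect_analysis()] result,
#' together with CSVs of every function estimate and envelope.
#'
#' @param report A `transect_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  td <- generics::tidy(report)
  jsonlite::write_json(
    list(
      summary = td,
      config = report$config[!vapply(report$config, is.null, logical(1))],
      window_wkt = window_to_wkt(report$window)
    ),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows"
  )
  lines <- c("# Transect analysis report", "")
  for (u in report$univariate) {
    if (!is.null(u$status) && u$status == "excluded") {
      lines <- c(lines, sprintf("* **%s**: %s", u$taxon, u$reason))
      next
    }
    lines <- c(lines, sprintf(
      "* **%s**: n = %d, density %.3g ind/m^2, %s, %s; driver: **%s** (%s)",
      u$taxon, u$n, u$density,
      if (u$classification$homogeneous) "homogeneous" else "inhomogeneous",
      u$classification$label, u$verdict$driver, u$verdict$evidence_notes
    ))
    write_fn_estimate(u$envelope,
                      file.path(dir, paste0("envelope_", u$taxon, ".csv")))
  }
  if (!is.null(report$bivariate)) {
    b <- report$bivariate
    lines <- c(lines, sprintf(
      "* **bivariate %s vs %s**: %s; driver: **%s** (%s)",
      b$taxa[1], b$taxa[2], b$classification$label, b$verdict$driver,
      b$verdict$evidence_notes
    ))
    write_fn_estimate(b$envelope, file.path(dir, "envelope_bivariate.csv"))
  }
  writeLines(lines, file.path(dir, "report.md"))
  invisible(dir)
}
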