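#' Marked planar point patterns
#'
#' Build a point pattern from a data frame of annotation coordinates. This is
#' the unit of analysis: one pattern per transect, optionally marked with a
#' taxon label per point (e.g. `"Pennatuloidea"`, `"Cerianthidae"`,
#' `"Hyalonema"`).
#'
#' @param data A data frame with numeric columns `x` and `y` (metres) and an
#'   optional `taxon` column (character or factor).
#' @param window A [window_polygon()] observation window. Every point must lie
#'   inside it (points on the boundary count as inside).
#' @param levels Optional character vector declaring the admissible taxon
#'   labels; defaults to the labels present in `data`.
#' @param allow_duplicates Duplicate coordinates are rejected by default (they
#'   are usually annotation errors); set `TRUE` to keep them.
#' @return A `point_pattern`: a [tibble::tibble()] with columns `x`, `y` (and
#'   `taxon` if marked) and attributes `window` and `mark_levels`.
#' @examples
#' w <- window_rect(c(0, 10), c(0, 2))
#' p <- point_pattern(data.frame(x = c(1, 2, 3), y = c(1, 1.5, 0.5)), w)
#' n_points(p)
#' @export
point_pattern <- function(data, window, levels = NULL, allow_duplicates = FALSE) {
  stopifnot(is.data.frame(data), inherits(window, "ppa_window"))
  if (!all(c("x", "y") %in% names(data))) {
    stop("`data` must have columns `x` and `y`", call. = FALSE)
  }
  x <- as.numeric(data$x)
  y <- as.numeric(data$y)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    bad <- which(!is.finite(x) | !is.finite(y))
    stop("non-finite coordinates in rows: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(x) > 0) {
    inside <- points_in_window(window, x, y)
    if (any(!inside)) {
      stop("points outside the observation window in rows: ",
           paste(which(!inside), collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(cbind(x, y))) {
      if (allow_duplicates) {
        warning("pattern contains duplicate coordinates", call. = FALSE)
      } else {
        stop("duplicate coordinates (set `allow_duplicates = TRUE` to keep them)",
             call. = FALSE)
      }
    }
  }
  out <- tibble::tibble(x = x, y = y)
  mark_levels <- NULL
  if ("taxon" %in% names(data)) {
    taxon <- as.character(data$taxon)
    mark_levels <- if (is.null(levels)) sort(unique(taxon)) else levels
    if (!all(taxon %in% mark_levels)) {
      stop("marks outside the declared label set: ",
           paste(setdiff(taxon, mark_levels), collapse = ", "), call. = FALSE)
    }
    out$taxon <- factor(taxon, levels = mark_levels)
  }
  structure(out,
    window = window, mark_levels = mark_levels,
    class = c("point_pattern", class(out))
  )
}

#' @rdname point_pattern
#' @param pattern A `point_pattern`.
#' @export
n_points <- function(pattern) nrow(pattern)

#' @rdname point_pattern
#' @export
pattern_window <- function(pattern) attr(pattern, "window")

#' @rdname point_pattern
#' @export
mark_levels <- function(pattern) attr(pattern, "mark_levels")

#' @rdname point_pattern
#' @export
is_marked <- function(pattern) "taxon" %in% names(pattern)

#' Restrict a marked pattern to one taxon
#'
#' @param pattern A marked `point_pattern`.
#' @param taxon A mark label present in the pattern's declared label set.
#' @return An unmarked `point_pattern` of that taxon's points.
#' @export
subset_taxon <- function(pattern, taxon) {
  if (!is_marked(pattern)) stop("pattern has no marks", call. = FALSE)
  if (!taxon %in% mark_levels(pattern)) {
    stop("no such mark label: ", taxon, call. = FALSE)
  }
  keep <- pattern$taxon == taxon
  new_pattern(pattern$x[keep], pattern$y[keep], pattern_window(pattern))
}

#' Drop marks from a pattern
#' @param pattern A `point_pattern`.
#' @return The unmarked superposition of all points.
#' @export
unmark <- function(pattern) {
  new_pattern(pattern$x, pattern$y, pattern_window(pattern))
}

#' @export
print.point_pattern <- function(x, ...) {
  w <- pattern_window(x)
  cat(sprintf("<point_pattern> n = %d%s in %.4g m^2 window\n", nrow(x),
              if (is_marked(x)) {
                paste0(" (", paste(sprintf("%s: %d", levels(x$taxon),
                                           tabulate(x$taxon, nlevels(x$taxon))),
                                   collapse = ", "), ")")
              } else "", w$area))
  NextMethod()
}

#' Nearest-neighbour distance summary
#'
#' Per-point nearest-neighbour distances (marks ignored), with their minimum
#' and mean. These are the raw (uncorrected) distances; no edge correction is
#' applied.
#'
#' @param pattern A `point_pattern` with at least 2 points.
#' @return An `nnd_summary`: list with `distances` (length n), `min`, `mean`,
#'   `n`. `tidy()` returns per-point rows; `glance()` a one-row summary.
#' @export
nnd_summary <- function(pattern) {
  n <- n_points(pattern)
  if (n < 2) stop("insufficient points: nearest-neighbour distances need n >= 2",
                  call. = FALSE)
  nn <- cpp_nn(pattern$x, pattern$y)
  if (any(nn$dist == 0)) {
    warning("zero nearest-neighbour distances (duplicate coordinates)",
            call. = FALSE)
  }
  structure(
    list(distances = nn$dist, which = nn$which, min = min(nn$dist),
         mean = mean(nn$dist), n = n),
    class = "nnd_summary"
  )
}

#' @export
print.nnd_summary <- function(x, ...) {
  cat(sprintf("<nnd_summary> n = %d, min %.4g m, mean %.4g m\n",
              x$n, x$min, x$mean))
  invisible(x)
}

#' Uniform intensity estimate
#'
#' The scalar density estimate n / |W| in individuals per square metre.
#'
#' @param pattern A `point_pattern`.
#' @return Density (ind m^-2).
#' @export
intensity_scalar <- function(pattern) {
  n_points(pattern) / pattern_window(pattern)$area
}

# Fast internal constructor for simulator output: coordinates are inside the
# window by construction, so validation is skipped.
new_pattern <- function(x, y, window, taxon = NULL, levels = NULL) {
  cols <- list(x = as.numeric(x), y = as.numeric(y))
  if (!is.null(taxon)) cols$taxon <- factor(taxon, levels = levels)
  out <- tibble::new_tibble(cols, nrow = length(cols$x))
  structure(out,
    window = window, mark_levels = levels,
    class = c("point_pattern", class(out))
  )
}
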