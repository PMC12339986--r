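#' Ripley's isotropic edge-correction weight
#'
#' For a point `(x, y)` inside the window and a radius `r`, the weight is the
#' reciprocal of the fraction of the circumference of the circle of radius `r`
#' centred at the point that lies inside the window. The weight is 1 when the
#' circle is fully interior and grows as the circle is cut by the boundary.
#'
#' For axis-aligned rectangular windows a closed form is used (arc deficits of
#' the cut half-planes with corner-overlap terms). For general simple polygons
#' the circle/edge intersection angles are computed exactly, the circle is cut
#' into arcs, and each arc is classified by testing its midpoint against the
#' polygon; this is exact for convex and non-convex rings alike.
#'
#' @param x,y Point coordinates (recycled to a common length with `r`).
#' @param r Radius in metres, `> 0`.
#' @param window A [window_polygon()] object.
#' @return Numeric vector of weights, each `>= 1`.
#' @examples
#' w <- window_rect(c(0, 10), c(0, 10))
#' isotropic_weight(5, 5, 1, w)   # 1: circle fully interior
#' isotropic_weight(5, 0, 0.5, w) # 2: semicircle inside
#' isotropic_weight(0, 0, 0.5, w) # 4: quarter circle inside
#' @export
isotropic_weight <- function(x, y, r, window) {
  stopifnot(inherits(window, "ppa_window"))
  k <- max(length(x), length(y), length(r))
  x <- rep_len(as.numeric(x), k)
  y <- rep_len(as.numeric(y), k)
  r <- rep_len(as.numeric(r), k)
  if (any(r <= 0)) stop("r must be > 0", call. = FALSE)
  if (!all(points_in_window(window, x, y))) {
    stop("edge-correction point outside the window", call. = FALSE)
  }
  frac <- if (window$is_rect) {
    rect_inside_fraction(x, y, r, window)
  } else {
    vapply(seq_len(k), function(i) {
      arc_inside_fraction(x[i], y[i], r[i], window)
    }, numeric(1))
  }
  if (any(frac <= 0)) {
    stop("undefined edge-correction weight: circle entirely outside the window",
         call. = FALSE)
  }
  1 / frac
}

# Closed-form inside fraction for an axis-aligned rectangle. The arc cut away
# by each boundary half-plane has half-angle acos(d/r) <= pi/2; arcs of
# adjacent edges overlap near a corner iff the corner lies inside the circle,
# with overlap angle acos(d1/r) + acos(d2/r) - pi/2. Arcs of opposite edges
# never overlap and no triple overlaps exist (half-angles are at most pi/2),
# so inclusion-exclusion over the four edges and four corners is exact for
# every radius.
rect_inside_fraction <- function(x, y, r, window) {
  b <- window$bbox
  d1 <- x - b["xmin"]
  d2 <- b["xmax"] - x
  d3 <- y - b["ymin"]
  d4 <- b["ymax"] - y
  cut_angle <- function(d, r) ifelse(d < r, 2 * acos(pmin(1, d / r)), 0)
  ext <- cut_angle(d1, r) + cut_angle(d2, r) +
    cut_angle(d3, r) + cut_angle(d4, r)
  corner <- function(da, db, r) {
    hit <- da^2 + db^2 < r^2
    ifelse(hit,
           acos(pmin(1, da / r)) + acos(pmin(1, db / r)) - pi / 2,
           0)
  }
  ext <- ext - corner(d1, d3, r) - corner(d1, d4, r) -
    corner(d2, d3, r) - corner(d2, d4, r)
  unname(1 - ext / (2 * pi))
}

# Exact arc decomposition for a general simple polygon: find all angles where
# the circle crosses an edge segment, sort them, and classify each arc by its
# midpoint.
arc_inside_fraction <- function(cx, cy, r, window) {
  vx <- window$x
  vy <- window$y
  m <- length(vx)
  x2 <- c(vx[-1], vx[1])
  y2 <- c(vy[-1], vy[1])
  angles <- numeric(0)
  for (e in seq_len(m)) {
    ax <- vx[e] - cx
    ay <- vy[e] - cy
    ex <- x2[e] - vx[e]
    ey <- y2[e] - vy[e]
    A <- ex^2 + ey^2
    B <- 2 * (ax * ex + ay * ey)
    C <- ax^2 + ay^2 - r^2
    disc <- B^2 - 4 * A * C
    if (disc <= 0) next
    sq <- sqrt(disc)
    for (t in c((-B - sq) / (2 * A), (-B + sq) / (2 * A))) {
      if (t >= 0 && t <= 1) {
        px <- ax + t * ex
        py <- ay + t * ey
        angles <- c(angles, atan2(py, px))
      }
    }
  }
  if (length(angles) == 0) {
    inside <- cpp_in_poly(cx + r, cy, vx, vy)
    return(if (inside) 1 else 0)
  }
  angles <- sort(unique(angles))
  bounds <- c(angles, angles[1] + 2 * pi)
  total <- 0
  for (a in seq_len(length(angles))) {
    mid <- (bounds[a] + bounds[a + 1]) / 2
    if (cpp_in_poly(cx + r * cos(mid), cy + r * sin(mid), vx, vy)) {
      total <- total + (bounds[a + 1] - bounds[a])
    }
  }
  total / (2 * pi)
}

# Vectorised pair weights used by the summary-function estimators: for each
# (point index, radius) pair, the isotropic weight at that point. Points come
# from validated patterns, so the in-window check is skipped.
pair_weights <- function(pattern, idx, d) {
  window <- pattern_window(pattern)
  x <- pattern$x[idx]
  y <- pattern$y[idx]
  frac <- if (window$is_rect) {
    rect_inside_fraction(x, y, d, window)
  } else {
    vapply(seq_along(x), function(i) {
      arc_inside_fraction(x[i], y[i], d[i], window)
    }, numeric(1))
  }
  if (any(frac <= 0)) {
    stop("undefined edge-correction weight: circle entirely outside the window",
         call. = FALSE)
  }
  1 / frac
}
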