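#' Observation windows for transect point patterns
#'
#' An observation window is a simple (non-self-intersecting) closed polygon in
#' planar metre coordinates: the footprint of an orthorectified video transect.
#' All geometry in the package (areas, edge corrections, quadrats, the
#' `r_max` scale rule) flows through it.
#'
#' @param vertices A data frame with numeric columns `x` and `y` giving the
#'   polygon vertices in order (metres). The ring may be given open or closed
#'   (a repeated last vertex is dropped).
#' @return An object of class `ppa_window`: a list with elements `x`, `y`
#'   (open vertex ring), `area` (m^2), `bbox` (`xmin`, `xmax`, `ymin`,
#'   `ymax`), and `is_rect` (`TRUE` for an axis-aligned rectangle, which
#'   enables closed-form edge corrections).
#' @examples
#' w <- window_polygon(data.frame(x = c(0, 3, 0), y = c(0, 0, 4)))
#' w$area # 6
#' @export
window_polygon <- function(vertices) {
  stopifnot(is.data.frame(vertices), all(c("x", "y") %in% names(vertices)))
  x <- as.numeric(vertices$x)
  y <- as.numeric(vertices$y)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("window vertices must be finite", call. = FALSE)
  }
  # drop explicit ring closure
  m <- length(x)
  if (m >= 2 && x[1] == x[m] && y[1] == y[m]) {
    x <- x[-m]
    y <- y[-m]
    m <- m - 1
  }
  if (m < 3) stop("a window needs at least 3 distinct vertices", call. = FALSE)
  if (anyDuplicated(cbind(x, y))) {
    stop("invalid geometry: duplicated window vertices", call. = FALSE)
  }
  if (!ring_is_simple(x, y)) {
    stop("invalid geometry: window polygon is self-intersecting", call. = FALSE)
  }
  area <- abs(shoelace(x, y))
  if (area <= 0) stop("invalid geometry: window area must be > 0", call. = FALSE)
  bbox <- c(xmin = min(x), xmax = max(x), ymin = min(y), ymax = max(y))
  if (bbox["xmax"] - bbox["xmin"] <= 0 || bbox["ymax"] - bbox["ymin"] <= 0) {
    stop("invalid geometry: degenerate bounding box", call. = FALSE)
  }
  is_rect <- m == 4 &&
    sum(x == bbox["xmin"]) == 2 && sum(x == bbox["xmax"]) == 2 &&
    sum(y == bbox["ymin"]) == 2 && sum(y == bbox["ymax"]) == 2 &&
    isTRUE(all.equal(area, unname((bbox["xmax"] - bbox["xmin"]) *
                                    (bbox["ymax"] - bbox["ymin"]))))
  structure(
    list(x = x, y = y, area = area, bbox = bbox, is_rect = is_rect),
    class = "ppa_window"
  )
}

#' @rdname window_polygon
#' @param xrange,yrange Length-2 numeric vectors giving the rectangle extent
#'   in metres.
#' @export
window_rect <- function(xrange = c(0, 10), yrange = c(0, 2)) {
  window_polygon(data.frame(
    x = c(xrange[1], xrange[2], xrange[2], xrange[1]),
    y = c(yrange[1], yrange[1], yrange[2], yrange[2])
  ))
}

#' @export
print.ppa_window <- function(x, ...) {
  cat(sprintf(
    "<ppa_window> %s, %d vertices, area %.4g m^2, bbox [%.3g, %.3g] x [%.3g, %.3g]\n",
    if (x$is_rect) "rectangle" else "polygon", length(x$x), x$area,
    x$bbox["xmin"], x$bbox["xmax"], x$bbox["ymin"], x$bbox["ymax"]
  ))
  invisible(x)
}

shoelace <- function(x, y) {
  j <- c(length(x), seq_len(length(x) - 1))
  sum(x[j] * y - x * y[j]) / 2
}

# Simplicity check: no two non-adjacent edges intersect; adjacent edges must
# not overlap beyond their shared vertex.
ring_is_simple <- function(x, y) {
  m <- length(x)
  x2 <- c(x[-1], x[1])
  y2 <- c(y[-1], y[1])
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      adjacent <- (j == i + 1) || (i == 1 && j == m)
      if (adjacent) next
      if (segments_intersect(
        x[i], y[i], x2[i], y2[i],
        x[j], y[j], x2[j], y2[j]
      )) {
        return(FALSE)
      }
    }
  }
  TRUE
}

segments_intersect <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  o <- function(px, py, qx, qy, rx, ry) {
    v <- (qx - px) * (ry - py) - (qy - py) * (rx - px)
    sign(v)
  }
  o1 <- o(ax, ay, bx, by, cx, cy)
  o2 <- o(ax, ay, bx, by, dx, dy)
  o3 <- o(cx, cy, dx, dy, ax, ay)
  o4 <- o(cx, cy, dx, dy, bx, by)
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(px, py, qx, qy, rx, ry) {
    o(px, py, qx, qy, rx, ry) == 0 &&
      rx >= min(px, qx) && rx <= max(px, qx) &&
      ry >= min(py, qy) && ry <= max(py, qy)
  }
  on_seg(ax, ay, bx, by, cx, cy) || on_seg(ax, ay, bx, by, dx, dy) ||
    on_seg(cx, cy, dx, dy, ax, ay) || on_seg(cx, cy, dx, dy, bx, by)
}

#' Window area
#'
#' Shoelace area of the window polygon (m^2).
#'
#' @param window A [window_polygon()] object.
#' @return Area in m^2.
#' @export
polygon_area <- function(window) {
  stopifnot(inherits(window, "ppa_window"))
  window$area
}

#' @keywords internal
shortest_bbox_edge <- function(window) {
  unname(min(
    window$bbox["xmax"] - window$bbox["xmin"],
    window$bbox["ymax"] - window$bbox["ymin"]
  ))
}

#' Maximum analysis distance for a window
#'
#' The spatial scale relevant to the analysis is approximately half the length
#' of the shortest window edge (for slender transects, half the transect
#' width). Summary functions refuse to evaluate beyond this distance unless
#' explicitly overridden.
#'
#' @param window A [window_polygon()] object.
#' @return Distance in metres.
#' @export
r_max_rule <- function(window) {
  shortest_bbox_edge(window) / 2
}

# Inside-or-on-boundary test; points within `tol` of an edge count as inside
# (transect outlines are traced around annotated organisms).
points_in_window <- function(window, x, y, tol = 1e-9) {
  inside <- cpp_in_poly(x, y, window$x, window$y)
  if (any(!inside)) {
    idx <- which(!inside)
    near <- dist_to_boundary(window, x[idx], y[idx]) <= tol
    inside[idx[near]] <- TRUE
  }
  inside
}

# Distance from points to the polygon boundary (minimum over edges).
dist_to_boundary <- function(window, x, y) {
  vx <- window$x
  vy <- window$y
  m <- length(vx)
  x2 <- c(vx[-1], vx[1])
  y2 <- c(vy[-1], vy[1])
  out <- rep(Inf, length(x))
  for (e in seq_len(m)) {
    ex <- x2[e] - vx[e]
    ey <- y2[e] - vy[e]
    len2 <- ex^2 + ey^2
    t <- ((x - vx[e]) * ex + (y - vy[e]) * ey) / len2
    t <- pmin(1, pmax(0, t))
    dx <- x - (vx[e] + t * ex)
    dy <- y - (vy[e] + t * ey)
    out <- pmin(out, sqrt(dx^2 + dy^2))
  }
  out
}

# Area of the window clipped to an axis-aligned rectangle, via
# Sutherland-Hodgman (valid for any simple subject polygon against a convex
# clipper). Used for quadrat expectations on polygonal windows.
clipped_area <- function(window, xmin, xmax, ymin, ymax) {
  px <- window$x
  py <- window$y
  clip_halfplane <- function(px, py, keep, intersect) {
    if (length(px) == 0) return(list(x = numeric(0), y = numeric(0)))
    nx <- numeric(0)
    ny <- numeric(0)
    m <- length(px)
    for (i in seq_len(m)) {
      j <- if (i == 1) m else i - 1
      cur_in <- keep(px[i], py[i])
      prev_in <- keep(px[j], py[j])
      if (cur_in) {
        if (!prev_in) {
          p <- intersect(px[j], py[j], px[i], py[i])
          nx <- c(nx, p[1]); ny <- c(ny, p[2])
        }
        nx <- c(nx, px[i]); ny <- c(ny, py[i])
      } else if (prev_in) {
        p <- intersect(px[j], py[j], px[i], py[i])
        nx <- c(nx, p[1]); ny <- c(ny, p[2])
      }
    }
    list(x = nx, y = ny)
  }
  ix <- function(x1, y1, x2, y2, v, axis) {
    t <- if (axis == "x") (v - x1) / (x2 - x1) else (v - y1) / (y2 - y1)
    c(x1 + t * (x2 - x1), y1 + t * (y2 - y1))
  }
  p <- list(x = px, y = py)
  p <- clip_halfplane(p$x, p$y, function(x, y) x >= xmin,
                      function(x1, y1, x2, y2) ix(x1, y1, x2, y2, xmin, "x"))
  p <- clip_halfplane(p$x, p$y, function(x, y) x <= xmax,
                      function(x1, y1, x2, y2) ix(x1, y1, x2, y2, xmax, "x"))
  p <- clip_halfplane(p$x, p$y, function(x, y) y >= ymin,
                      function(x1, y1, x2, y2) ix(x1, y1, x2, y2, ymin, "y"))
  p <- clip_halfplane(p$x, p$y, function(x, y) y <= ymax,
                      function(x1, y1, x2, y2) ix(x1, y1, x2, y2, ymax, "y"))
  if (length(p$x) < 3) return(0)
  abs(shoelace(p$x, p$y))
}
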