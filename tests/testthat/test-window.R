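test_that("polygon areas match the shoelace value", {
  expect_equal(polygon_area(rect_10x2()), 20)
  tri <- window_polygon(data.frame(x = c(0, 3, 0), y = c(0, 0, 4)))
  expect_equal(polygon_area(tri), 6)

  set.seed(42)
  # random star-shaped octagon (sorted angles guarantee a simple ring)
  th <- sort(runif(8, 0, 2 * pi))
  rad <- runif(8, 0.5, 2)
  x <- rad * cos(th)
  y <- rad * sin(th)
  w <- window_polygon(data.frame(x = x, y = y))
  expect_equal(polygon_area(w), oracle_polygon_area(x, y), tolerance = 1e-12)
})

test_that("area is invariant under rigid motions and vertex reversal", {
  set.seed(7)
  th <- sort(runif(8, 0, 2 * pi))
  rad <- runif(8, 0.5, 2)
  x <- rad * cos(th)
  y <- rad * sin(th)
  a0 <- polygon_area(window_polygon(data.frame(x = x, y = y)))
  # translation
  expect_equal(polygon_area(window_polygon(data.frame(x = x + 11, y = y - 3))),
               a0)
  # rotation
  phi <- 0.7
  xr <- x * cos(phi) - y * sin(phi)
  yr <- x * sin(phi) + y * cos(phi)
  expect_equal(polygon_area(window_polygon(data.frame(x = xr, y = yr))), a0,
               tolerance = 1e-12)
  # reversal
  expect_equal(polygon_area(window_polygon(data.frame(x = rev(x), y = rev(y)))),
               a0)
})

test_that("degenerate and self-intersecting rings are rejected", {
  expect_error(window_polygon(data.frame(x = c(0, 1), y = c(0, 1))),
               "at least 3")
  # bow-tie
  expect_error(
    window_polygon(data.frame(x = c(0, 1, 0, 1), y = c(0, 1, 1, 0))),
    "self-intersecting"
  )
})

test_that("r_max rule is half the shortest bbox edge", {
  expect_equal(r_max_rule(rect_10x2()), 1)
  expect_equal(r_max_rule(window_rect(c(0, 5), c(0, 8))), 2.5)
})

test_that("windows round-trip through WKT and GeoJSON", {
  w <- window_polygon(data.frame(x = c(0, 10.5, 10, 0.25),
                                 y = c(0, 0.1, 2, 1.9)))
  w2 <- window_from_wkt(window_to_wkt(w))
  expect_equal(w2$x, w$x)
  expect_equal(w2$y, w$y)
  gj <- sprintf(
    '{"type": "Polygon", "coordinates": [[%s]]}',
    paste(sprintf("[%g, %g]", c(w$x, w$x[1]), c(w$y, w$y[1])), collapse = ", ")
  )
  w3 <- window_from_geojson(gj)
  expect_equal(w3$area, w$area)
})

test_that("rectangle clipping recovers quadrat areas on polygons", {
  tri <- window_polygon(data.frame(x = c(0, 4, 0), y = c(0, 0, 4)))
  # left half of the right triangle: trapezoid of area 6
  expect_equal(transectppa:::clipped_area(tri, 0, 2, 0, 4), 6)
  expect_equal(transectppa:::clipped_area(tri, 2, 4, 0, 4), 2)
  expect_equal(transectppa:::clipped_area(tri, 5, 6, 0, 4), 0)
})
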