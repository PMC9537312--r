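test_that("polygon_area handles classic shapes and rejects bowties", {
  square <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(polygon_area(square), 1)
  # orientation-independent
  expect_equal(polygon_area(square[4:1, ]), 1)
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  hexagon <- data.frame(x = cos(th), y = sin(th))
  expect_equal(polygon_area(hexagon), 3 * sqrt(3) / 2, tolerance = 1e-12)
  th64 <- seq(0, 2 * pi, length.out = 65)[-65]
  gon64 <- data.frame(x = 25 * cos(th64), y = 25 * sin(th64))
  expect_equal(polygon_area(gon64), 64 / 2 * 625 * sin(2 * pi / 64), tolerance = 1e-12)
  expect_lt(abs(polygon_area(gon64) - pi * 625) / (pi * 625), 0.005)
  bowtie <- data.frame(x = c(0, 1, 0, 1), y = c(0, 1, 1, 0))
  expect_error(polygon_area(bowtie), class = "glenocard_error_geometry")
  expect_error(polygon_area(square[1:2, ]), class = "glenocard_error_domain")
})

test_that("circle_polygon_area reproduces closed forms", {
  r <- 25
  # containment: huge square around the disc
  big <- data.frame(x = c(-99, 99, 99, -99), y = c(-99, -99, 99, 99))
  expect_equal(circle_polygon_area(big, c(0, 0), r), pi * r^2, tolerance = 1e-12)
  # disjoint
  far <- data.frame(x = c(100, 110, 110, 100), y = c(0, 0, 10, 10))
  expect_equal(circle_polygon_area(far, c(0, 0), r), 0)
  # circular segment, chord at d = r/2
  d <- r / 2
  seg <- data.frame(x = c(d, 99, 99, d), y = c(-99, -99, 99, 99))
  closed <- r^2 * acos(d / r) - d * sqrt(r^2 - d^2)
  expect_equal(circle_polygon_area(seg, c(0, 0), r), closed, tolerance = 1e-10)
  # half the disc via a chord through the centre
  half <- data.frame(x = c(0, 99, 99, 0), y = c(-99, -99, 99, 99))
  expect_equal(circle_polygon_area(half, c(0, 0), r), pi * r^2 / 2, tolerance = 1e-10)
  # polygon fully inside the disc: plain shoelace area
  sq <- data.frame(x = c(-3, 3, 3, -3), y = c(-3, -3, 3, 3))
  expect_equal(circle_polygon_area(sq, c(0, 0), r), 36, tolerance = 1e-12)
})

test_that("circle_polygon_area agrees with rasterization on random convex polygons", {
  r <- 25
  set.seed(42)
  for (rep in 1:8) {
    pts <- matrix(stats::runif(24, -1.4 * r, 1.4 * r), ncol = 2)
    hull <- pts[grDevices::chull(pts), ]
    poly <- data.frame(x = hull[, 1], y = hull[, 2])
    exact <- circle_polygon_area(poly, c(0, 0), r)
    approx <- raster_circle_polygon_area(poly, c(0, 0), r, px = 0.05)
    # within 0.2 percentage points of the disc area
    expect_lt(abs(exact - approx) / (pi * r^2), 0.002)
  }
})

test_that("intersection area is invariant under rigid motion of the scene", {
  r <- 25
  set.seed(7)
  pts <- matrix(stats::runif(16, -30, 30), ncol = 2)
  hull <- pts[grDevices::chull(pts), ]
  poly <- data.frame(x = hull[, 1], y = hull[, 2])
  base <- circle_polygon_area(poly, c(0, 0), r)
  for (i in 1:5) {
    th <- stats::runif(1, 0, 2 * pi); tx <- stats::runif(2, -50, 50)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    moved <- as.data.frame(t(R %*% t(as.matrix(poly))) +
                             matrix(tx, nrow(poly), 2, byrow = TRUE))
    names(moved) <- c("x", "y")
    ctr <- as.numeric(R %*% c(0, 0) + tx)
    expect_equal(circle_polygon_area(moved, ctr, r), base, tolerance = 1e-9)
  }
})

test_that("half-plane and box clipping keep the right region", {
  sq <- list(x = c(0, 4, 4, 0), y = c(0, 0, 4, 4))
  p <- glenocard:::clip_halfplane(sq$x, sq$y, 1, 0, 2)   # keep x <= 2
  expect_equal(abs(glenocard:::shoelace(p$x, p$y)), 8)
  p2 <- glenocard:::clip_box(sq$x, sq$y, 1, 3, 1, 2)
  expect_equal(abs(glenocard:::shoelace(p2$x, p2$y)), 2)
  # clip everything away
  p3 <- glenocard:::clip_halfplane(sq$x, sq$y, 1, 0, -1)
  expect_length(p3$x, 0)
})

test_that("segment fraction and chord offset are mutually inverse", {
  r <- 25
  expect_equal(segment_fraction(r / 2, r), 0.1955, tolerance = 1e-4)
  expect_equal(segment_fraction(0, r), 0.5)
  expect_equal(segment_fraction(r, r), 0)
  for (f in c(0.02, 0.1955, 0.35, 0.49)) {
    expect_equal(segment_fraction(chord_offset(f, r), r), f, tolerance = 1e-9)
  }
  # monotone decreasing in d
  fr <- vapply(seq(-24, 24, length.out = 30), segment_fraction, numeric(1), r = r)
  expect_true(all(diff(fr) < 0))
})
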