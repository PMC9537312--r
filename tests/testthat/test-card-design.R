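test_that("quarter_area matches quadrature and has the bijection endpoints", {
  expect_equal(quarter_area(0, 25), 0)
  expect_equal(quarter_area(25, 25), pi * 625 / 4)
  for (x in c(0.5, 3.94, 12.5, 20, 24.9)) {
    expect_equal(quarter_area(x, 25), quarter_area_quad(x, 25), tolerance = 1e-9)
  }
  expect_equal(quarter_area(1.615, 4), 2 * pi, tolerance = 1e-2)
  expect_equal(quarter_area(3.94, 25), pi * 625 / 20, tolerance = 0.1)
  # strictly increasing
  xs <- seq(0, 25, length.out = 101)
  expect_true(all(diff(quarter_area(xs, 25)) > 0))
  expect_error(quarter_area(-1, 25), class = "glenocard_error_domain")
  expect_error(quarter_area(26, 25), class = "glenocard_error_domain")
  expect_error(quarter_area(1, -2), class = "glenocard_error_domain")
})

test_that("quarter_area composed with root-finding is the identity", {
  r <- 25
  for (x in c(0.1, 2, 7.7, 13, 21, 24.5)) {
    area <- quarter_area(x, r)
    back <- bisect(function(t) quarter_area(t, r) - area, 0, r)
    expect_lt(abs(back - x), 1e-9 * r)
  }
})

test_that("cut points reproduce the published card and the bisection oracle", {
  cuts <- solve_cut_points(25, 5)
  expect_length(cuts, 4)
  expect_true(all(diff(cuts) > 0) && all(cuts > 0 & cuts < 25))
  # published values are printed at 2 dp (mixed rounding/truncation), so
  # compare at one unit in the last printed digit
  expect_equal(cuts, c(3.94, 7.99, 12.29, 17.17), tolerance = 0.011)
  # residual of the defining equation
  resid <- abs(quarter_area(cuts, 25) - (1:4) * pi * 625 / 20)
  expect_true(all(resid <= 1e-10 * 625))
  # r = 4, n = 2 worked example
  expect_equal(solve_cut_points(4, 2), 1.615, tolerance = 1e-3)
  expect_identical(solve_cut_points(25, 1), numeric(0))
  # against an independent quadrature + bisection oracle
  k1_oracle <- bisect(function(t) quarter_area_quad(t, 25) - pi * 625 / 20, 0, 25)
  expect_equal(cuts[1], k1_oracle, tolerance = 1e-8)
  expect_error(solve_cut_points(-1, 5), class = "glenocard_error_domain")
  expect_error(solve_cut_points(25, 0), class = "glenocard_error_domain")
})

test_that("cut points and split ordinates are scale-equivariant", {
  base_cuts <- solve_cut_points(1, 5)
  base_ords <- solve_split_ordinates(1, base_cuts)
  for (c_scale in c(0.1, 2, 25)) {
    expect_equal(solve_cut_points(c_scale, 5), c_scale * base_cuts,
                 tolerance = 1e-10)
    expect_equal(solve_split_ordinates(c_scale, c_scale * base_cuts),
                 c_scale * base_ords, tolerance = 1e-9)
  }
  # the r = 1 solution is the r = 25 solution divided by 25
  expect_equal(base_cuts, solve_cut_points(25, 5) / 25, tolerance = 1e-12)
  expect_equal(base_cuts, c(0.1576, 0.3196, 0.4916, 0.6868), tolerance = 1e-3)
})

test_that("strip_area_below matches its quadrature oracle and saturates", {
  cuts <- solve_cut_points(25, 5)
  expect_equal(strip_area_below(0, cuts[1], cuts[2], 25), 0)
  full <- quarter_area(cuts[2], 25) - quarter_area(cuts[1], 25)
  expect_equal(strip_area_below(30, cuts[1], cuts[2], 25), full, tolerance = 1e-12)
  # monotone non-decreasing in y
  areas <- vapply(seq(0, 26, length.out = 40), strip_area_below,
                  numeric(1), a = cuts[4], b = 25, r = 25)
  expect_true(all(diff(areas) >= -1e-12))
  # arc-bounded outer strip: the published split ordinate halves it
  expect_equal(strip_area_below(6.51, cuts[4], 25, 25), pi * 625 / 40,
               tolerance = 1e-2 * pi * 625 / 40)
  for (y in c(2, 6.51, 15, 24)) {
    expect_equal(strip_area_below(y, cuts[4], 25, 25),
                 strip_area_quad(y, cuts[4], 25, 25), tolerance = 1e-9)
    expect_equal(strip_area_below(y, 2, 10, 25),
                 strip_area_quad(y, 2, 10, 25), tolerance = 1e-9)
  }
  expect_error(strip_area_below(1, 5, 5, 25), class = "glenocard_error_domain")
  expect_error(strip_area_below(1, 5, 26, 25), class = "glenocard_error_domain")
})

test_that("split ordinates halve every strip, arc-aware", {
  cuts <- solve_cut_points(25, 5)
  ords <- solve_split_ordinates(25, cuts)
  expect_length(ords, 5)
  edges <- c(0, cuts, 25)
  half <- pi * 625 / 40
  for (i in 1:5) {
    expect_lt(abs(strip_area_below(ords[i], edges[i], edges[i + 1], 25) - half),
              1e-10 * 625)
  }
  # first strip is a pure rectangle: closed form (pi r^2 / 8n) / width
  expect_equal(ords[1], half / cuts[1], tolerance = 1e-12)
  # the outermost ordinate is NOT the rectangle value: the arc matters there
  expect_gt(abs(ords[5] - half / (25 - cuts[4])), 0.2)
  # n = 1 degenerate card on the unit radius, against the bisection oracle
  y1 <- solve_split_ordinates(1, numeric(0))
  y1_oracle <- bisect(function(t) strip_area_quad(t, 0, 1, 1) - pi / 8, 0, 1)
  expect_equal(y1, y1_oracle, tolerance = 1e-8)
  expect_equal(y1, 0.4040, tolerance = 1e-4)
  expect_error(solve_split_ordinates(25, c(5, 3)), class = "glenocard_error_domain")
})

test_that("build_card tiles the disc with 8n equal cells", {
  card <- std_card()
  expect_s3_class(card, "card_geometry")
  expect_equal(nrow(card$cells), 40L)
  expect_equal(sum(card$cells$area_mm2), pi * 625, tolerance = 1e-9)
  # independent quadrature oracle for every cell area
  areas <- vapply(card$cells$id, function(id) cell_area_quad(card, id), numeric(1))
  expect_true(all(abs(areas - pi * 625 / 40) <= 1e-8 * pi * 625 / 40))
  expect_equal(pi * 625 / 40, 49, tolerance = 0.1 / 49)
  # degenerate n = 1 card
  card1 <- build_card(card_spec(50, 1))
  expect_equal(nrow(card1$cells), 8L)
  areas1 <- vapply(card1$cells$id, function(id) cell_area_quad(card1, id), numeric(1))
  expect_true(all(abs(areas1 - pi * 625 / 8) <= 1e-8 * pi * 625 / 8))
})

test_that("cell boundaries are simple, inside the disc, and axis-symmetric", {
  card <- std_card()
  r <- card$spec$radius_mm
  polys <- lapply(card$cells$id, function(id) cell_polygon(card, id))
  for (p in polys) {
    expect_true(all(p$x_mm^2 + p$y_mm^2 <= r^2 * (1 + 1e-9)))
  }
  # shoelace area of the discretized boundary approaches the exact cell area
  sh <- vapply(polys, function(p) polygon_area(p, validate = FALSE), numeric(1))
  expect_true(all(abs(sh - pi * r^2 / 40) < 1e-3 * pi * r^2 / 40))
  # a random sample of boundaries is simple (non-self-intersecting)
  for (id in c(1, 8, 17, 26, 40)) {
    p <- cell_polygon(card, id, arc_points = 24)
    expect_no_error(polygon_area(p, validate = TRUE))
  }
  # reflection symmetry: the (strip, layer) area multiset is quadrant-invariant
  by_quadrant <- split(card$cells$area_mm2,
                       paste(card$cells$strip, card$cells$layer))
  expect_true(all(vapply(by_quadrant, function(a) max(a) - min(a) < 1e-12, TRUE)))
  # mirrored centroids coincide up to sign flips
  cen <- t(vapply(polys, function(p) c(mean(p$x_mm), mean(p$y_mm)), numeric(2)))
  q1 <- card$cells$quadrant == 1
  for (q in 2:4) {
    s <- list(`2` = c(-1, 1), `3` = c(-1, -1), `4` = c(1, -1))[[as.character(q)]]
    m <- card$cells$quadrant == q
    expect_equal(cen[m, 1] * s[1], cen[q1, 1], tolerance = 1e-9)
    expect_equal(cen[m, 2] * s[2], cen[q1, 2], tolerance = 1e-9)
  }
})
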