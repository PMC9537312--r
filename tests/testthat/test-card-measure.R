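test_that("registration is the similarity transform onto the fitted circle", {
  card <- std_card()
  reg0 <- register_card(card, as_circle(c(0, 0), 25))
  expect_equal(reg0$scale, 1)
  expect_equal(reg0$translation, c(0, 0))
  reg <- register_card(card, as_circle(c(10, -3), 12.5))
  expect_equal(reg$scale, 0.5)
  expect_equal(reg$translation, c(10, -3))
})

test_that("the half-grid reading rule follows the tolerance protocol", {
  expect_equal(grid_reading(0.6, 2.5, 0.5), 1.75)
  expect_equal(grid_reading(0.4, 2.5, 0.5), 0.75)
  expect_equal(grid_reading(0.5, 2.5, 0.5), 1.25)
  # monotone non-decreasing in the fill fraction
  reads <- grid_reading(seq(0.01, 0.99, by = 0.01))
  expect_true(all(diff(reads) >= 0))
  expect_error(grid_reading(0.6, 2.5, 1.5), class = "glenocard_error_domain")
  expect_error(grid_reading(0, 2.5, 0.5), class = "glenocard_error_domain")
  expect_error(grid_reading(1, 2.5, 0.5), class = "glenocard_error_domain")
})

test_that("quantization bound matches brute-force maximization", {
  expect_equal(quantization_error_bound(1, 2.5, 0.5), 0.75)
  expect_equal(quantization_error_bound(4, 2.5, 0.5), 3.0)
  expect_equal(quantization_error_bound(0, 2.5, 0.5), 0)
  # alpha at the upper edge: bound becomes alpha itself
  expect_equal(quantization_error_bound(1, 2.5, 1.25), 1.25)
  for (alpha in c(0, 0.25, 0.5, 1.0, 1.25)) {
    expect_equal(quantization_error_bound(1, 2.5, alpha),
                 reading_rule_max_error(2.5, alpha), tolerance = 1e-3)
  }
})

test_that("grid counting recognizes full, empty and aligned regions", {
  card <- std_card()
  reg <- register_card(card, as_circle(c(0, 0), 25))
  big <- data.frame(x_mm = c(-99, 99, 99, -99), y_mm = c(-99, -99, 99, 99))
  rd <- count_grids(card, reg, big)
  expect_equal(rd$full_count, 40L)
  expect_equal(nrow(rd$partials), 0L)
  expect_equal(defect_percent(rd), 100)
  far <- data.frame(x_mm = c(100, 120, 120), y_mm = c(0, 0, 20))
  rd0 <- count_grids(card, reg, far)
  expect_equal(rd0$full_count, 0L)
  expect_equal(defect_percent(rd0), 0)
  expect_equal(defect_percent(count_grids(card, reg, NULL)), 0)
  # quadrant 4 exactly: its 2n cells are full, nothing else is touched
  quad4 <- data.frame(x_mm = c(0, 99, 99, 0), y_mm = c(-99, -99, 0, 0))
  rd4 <- count_grids(card, reg, quad4)
  expect_equal(rd4$full_count, 10L)
  expect_equal(nrow(rd4$partials), 0L)
  expect_equal(defect_percent(rd4), 25)
})

test_that("defect percent adds full units and partial readings", {
  card <- std_card()
  reg <- register_card(card, as_circle(c(0, 0), 25))
  # chord through two cells' worth of area: percent = full*2.5 + readings
  d <- chord_offset(0.10, 25)
  seg <- data.frame(x_mm = c(d, 99, 99, d), y_mm = c(-99, -99, 99, 99))
  rd <- count_grids(card, reg, seg)
  expect_equal(defect_percent(rd),
               rd$full_count * 2.5 + sum(rd$partials$read_pct))
  expect_true(all(rd$partials$read_pct %in% c(0.75, 1.25, 1.75)))
  expect_true(all(rd$partials$fill_fraction > 0 & rd$partials$fill_fraction < 1))
})

test_that("card percent stays within the quantization bound of the truth", {
  card <- std_card()
  for (i in 1:50) {
    f <- 0.02 + 0.4 * ((i * 17) %% 50) / 50
    shape <- if (i %% 2 == 0) "chord" else "bite"
    ph <- make_phantom(25, f, shape, seed = i)
    res <- measure_card(card, ph$circle, ph$defect)
    expect_lte(abs(res$defect_percent - 100 * ph$true_fraction),
               res$error_bound_pct + 0.05)
  }
})

test_that("card percent is invariant under rigid translation of the scene", {
  card <- std_card()
  ph <- make_phantom(25, 0.17, "bite", seed = 5)
  base <- measure_card(card, ph$circle, ph$defect)$defect_percent
  for (tx in list(c(13, -8), c(-40, 2.5))) {
    moved <- data.frame(x_mm = ph$defect$x_mm + tx[1],
                        y_mm = ph$defect$y_mm + tx[2])
    circ <- as_circle(ph$circle$center + tx, 25)
    expect_equal(measure_card(card, circ, moved)$defect_percent, base)
  }
  # and under scaling of the whole scene (card registration absorbs it)
  half <- data.frame(x_mm = ph$defect$x_mm / 2, y_mm = ph$defect$y_mm / 2)
  expect_equal(measure_card(card, as_circle(c(0, 0), 12.5), half)$defect_percent,
               base, tolerance = 1e-9)
})

test_that("card rotation changes partial cells but respects the bound", {
  card <- std_card()
  ph <- make_phantom(25, 0.22, "chord", seed = 2)
  for (rot in c(0, 0.3, 1.1)) {
    res <- measure_card(card, ph$circle, ph$defect, rotation_rad = rot)
    expect_lte(abs(res$defect_percent - 100 * ph$true_fraction),
               res$error_bound_pct + 0.05)
  }
})
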