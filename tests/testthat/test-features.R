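make_well <- function(x0, y0, amp, sx = 1, sy = 1, theta = 0)
  data.frame(x0 = x0, y0 = y0, amp = amp, sx = sx, sy = sy, theta = theta)

test_that("a single central well is classified as type-1 depression", {
  x <- seq(-8, 8, length.out = 101)
  f <- function(X, Y) -exp(-(X^2 + Y^2))
  e <- epd(x, x, outer(x, x, f))
  ft <- extract_features(e)
  expect_equal(ft$cminV, -1, tolerance = 1e-3)
  expect_equal(ft$cmaxV, 0, tolerance = 1e-3)
  # outside minimum is the Gaussian tail just beyond the footprint corner
  expect_equal(ft$ominV, 0, tolerance = 0.02)
  expect_equal(ft$epd_type, "depression_type1")
})

test_that("tripole features agree with the brute-force oracle", {
  th <- 70 * pi / 180
  comp <- rbind(make_well(0, 0, -0.8),
                make_well(3 * cos(th), 3 * sin(th), -1.2),
                make_well(-3 * cos(th), -3 * sin(th), -1.2))
  s <- make_synthetic_epd(comp, n = 161)
  ft <- extract_features(s$epd)
  expect_equal(ft$epd_type, "depression_type2")
  expect_equal(s$truth$epd_type, "depression_type2")
  expect_lt(ft$ominV, ft$cminV)
  expect_lt(ft$cminV, 0)
  expect_equal(ft$cminV, s$truth$cminV, tolerance = 0.02)
  expect_equal(ft$ominV, s$truth$ominV, tolerance = 0.02)
  expect_equal(ft$angmin, 70, tolerance = 1.5)
  expect_equal(s$truth$angmin, 70, tolerance = 0.5)
})

test_that("adding a constant shifts potentials and leaves angles unchanged", {
  th <- 55 * pi / 180
  comp <- rbind(make_well(0, 0, -0.6, sx = 2, sy = 1),
                make_well(3 * cos(th), 3 * sin(th), -1),
                make_well(-3 * cos(th), -3 * sin(th), -1))
  e <- make_synthetic_epd(comp, n = 121)$epd
  f1 <- extract_features(e)
  e2 <- e; e2$values <- e$values - 0.37
  f2 <- extract_features(e2)
  expect_equal(f2$cminV, f1$cminV - 0.37)
  expect_equal(f2$cmaxV, f1$cmaxV - 0.37)
  expect_equal(f2$ominV, f1$ominV - 0.37)
  expect_equal(f2$angmin, f1$angmin)
  expect_equal(f2$ellipse_angle, f1$ellipse_angle)
})

test_that("extremum angles follow their defining geometry", {
  e1 <- make_synthetic_epd(rbind(make_well(0, 3, -1)), n = 161)$epd
  expect_equal(extremum_angle(e1, "min", "outside"), 90, tolerance = 0.5)
  e2 <- make_synthetic_epd(rbind(make_well(-2.6, 2.6, -1)), n = 161)$epd
  expect_equal(extremum_angle(e2, "min", "outside"), 135, tolerance = 0.5)
  # no qualifying extremum: an undefined-feature signal, not an error
  e3 <- make_synthetic_epd(rbind(make_well(0, -3, -1)), n = 81)$epd
  expect_true(is.na(extremum_angle(e3, "min", "outside")))
})

test_that("ellipse orientation tracks the principal axis of the depression", {
  well <- function(theta) rbind(make_well(0, 0, -1, sx = 2.5, sy = 0.9,
                                          theta = theta))
  e0 <- make_synthetic_epd(well(0), n = 161)$epd
  expect_equal(as.numeric(ellipse_angle(e0)), 0, tolerance = 2)
  e58 <- make_synthetic_epd(well(58.2), n = 161)$epd
  expect_equal(as.numeric(ellipse_angle(e58)), 58.2, tolerance = 2)
  # circular well: angle reported but flagged degenerate
  ec <- make_synthetic_epd(rbind(make_well(0, 0, -1, sx = 1.2, sy = 1.2)),
                           n = 161)$epd
  a <- ellipse_angle(ec)
  expect_false(is.na(a))
  expect_lt(attr(a, "axis_ratio"), 1.2)
})

test_that("feature extraction is rotation-equivariant on synthetic EPDs", {
  base_angle <- 40
  for (delta in c(15, 30, 60)) {
    th <- (base_angle + delta) * pi / 180
    comp <- rbind(make_well(0, 0, -0.7, sx = 2.4, sy = 1,
                            theta = base_angle + delta),
                  make_well(3.1 * cos(th), 3.1 * sin(th), -1.1),
                  make_well(-3.1 * cos(th), -3.1 * sin(th), -1.1))
    ft <- extract_features(make_synthetic_epd(comp, n = 161)$epd)
    expect_equal(ft$angmin, base_angle + delta, tolerance = 1.5)
    expect_equal(ft$ellipse_angle, base_angle + delta, tolerance = 2.5)
  }
})

test_that("classification partitions feature space as defined", {
  expect_equal(classify_epd(-1.37, -0.1, -0.9), "depression_type1")
  expect_equal(classify_epd(-0.75, -0.07, -0.95), "depression_type2")
  expect_equal(classify_epd(-0.5, 1.04, -1.7), "elevation")
  # elevation wins regardless of the minima ordering
  expect_equal(classify_epd(-2, 0.01, -1), "elevation")
  # all EPDs with cmaxV <= 0 fall in exactly one depression class
  set.seed(1)
  for (i in 1:50) {
    cmin <- -runif(1); omin <- -runif(1); cmax <- cmin + runif(1) * abs(cmin)
    cls <- classify_epd(cmin, min(cmax, 0), omin)
    expect_true(cls %in% c("depression_type1", "depression_type2"))
    expect_equal(cls == "depression_type2", omin < cmin)
  }
})
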