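test_that("default ranges reproduce the canonical sampling table", {
  rg <- default_ranges()
  expect_equal(unname(rg$min[c("ROT", "g_b")]), c(60, 3.25))
  expect_equal(unname(rg$mean[c("ROT", "g_b")]), c(100, 6.5))
  expect_equal(unname(rg$max[c("ROT", "g_b")]), c(140, 9.75))
  expect_equal(unname(rg$min[c("g_il", "g_el", "g_it", "g_et", "g_in", "g_en")]),
               c(1.2, 1.2, 0.12, 0.8, 0.05, 0.5))
  expect_equal(unname(rg$mean[c("g_il", "g_el", "g_it", "g_et", "g_in", "g_en")]),
               c(2.4, 2.4, 0.24, 1.6, 0.1, 1.0))
  expect_equal(unname(rg$max[c("g_il", "g_el", "g_it", "g_et", "g_in", "g_en")]),
               c(3.6, 3.6, 0.36, 2.4, 0.15, 1.5))
  # mean +/- 50% structure: max/min = 3 for every conductivity row
  cond <- setdiff(rg$table$name, "ROT")
  expect_equal(unname(rg$max[cond] / rg$min[cond]), rep(3, length(cond)))
  expect_equal(unname(rg$mean), unname((rg$min + rg$max) / 2))
})

test_that("latin hypercube stratifies every dimension and is reproducible", {
  rg <- default_ranges()
  d4 <- latin_hypercube(4, rg, seed = 42)
  for (j in seq_len(ncol(d4$points))) {
    strata <- findInterval(sort(d4$points[, j]), c(0, .25, .5, .75),
                           rightmost.closed = FALSE)
    expect_equal(strata, 1:4)
  }
  expect_identical(latin_hypercube(4, rg, seed = 42)$points, d4$points)
  expect_false(identical(latin_hypercube(4, rg, seed = 43)$points, d4$points))
  expect_error(latin_hypercube(1, rg), "invalid design")

  # stratified sampling keeps per-dimension means very close to 1/2
  d250 <- latin_hypercube(250, rg, seed = 7)
  mu <- colMeans(d250$points)
  expect_true(all(mu > 0.48 & mu < 0.52))

  # marginal uniformity: KS statistic below the 1% critical value for n = 50
  d50 <- latin_hypercube(50, rg, seed = 3)
  for (j in seq_len(ncol(d50$points))) {
    ks <- max(abs(sort(d50$points[, j]) - (seq_len(50) - 0.5) / 50)) + 0.5 / 50
    expect_lt(ks, 1.63 / sqrt(50))
  }
})

test_that("denormalize maps the unit cube onto the physical box linearly", {
  rg <- default_ranges()
  u <- setNames(rep(0.5, 8), input_names())
  expect_equal(denormalize(u, rg)[["g_il"]], 2.4)
  expect_equal(denormalize(setNames(0, "ROT"), rg)[["ROT"]], 60)
  expect_equal(denormalize(setNames(1, "ROT"), rg)[["ROT"]], 140)
  expect_error(denormalize(setNames(1.2, "ROT"), rg), "\\[0, 1\\]")
  # exact round trip
  set.seed(1)
  U <- matrix(runif(40), 5, 8, dimnames = list(NULL, input_names()))
  expect_equal(normalize_inputs(denormalize(U, rg), rg), U, tolerance = 1e-14)
})

test_that("bulk conductivity and velocity ratios match the derived values", {
  g <- mean_conductivities()
  expect_equal(signif(bulk_conductivity_ratio(g, "l", "t"), 2), 2.6)
  expect_equal(signif(bulk_conductivity_ratio(g, "t", "n"), 2), 1.7)
  expect_equal(signif(velocity_ratio(g, "l", "t"), 2), 2.4)
  expect_equal(signif(velocity_ratio(g, "t", "n"), 2), 1.5)
  expect_equal(bulk_conductivity_ratio(g, "l", "l"), 1)
  expect_equal(velocity_ratio(g, "n", "n"), 1)
  # scale invariance
  g2 <- conductivity_set(2 * g[["g_il"]], 2 * g[["g_el"]], 2 * g[["g_it"]],
                         2 * g[["g_et"]], 2 * g[["g_in"]], 2 * g[["g_en"]],
                         2 * g[["g_b"]])
  expect_equal(bulk_conductivity_ratio(g2, "l", "t"),
               bulk_conductivity_ratio(g, "l", "t"))
  expect_equal(velocity_ratio(g2, "l", "n"), velocity_ratio(g, "l", "n"))
})

test_that("literature summary reproduces the printed mean/std rows", {
  sm <- literature_summary()
  # printed means at 1 d.p.; g_il is exactly 2.05, a round-half case
  expect_true(all(abs(unname(sm$mean) -
                        c(2.1, 2.7, 0.3, 1.6, 0.1, 1.2)) <= 0.0501))
  expect_equal(round(sm$mean[["g_it"]], 2), 0.28)
  expect_equal(round(sm$mean[["g_in"]], 2), 0.11)
  # printed std row at 1 d.p. (g_it at 2 d.p. as printed)
  expect_equal(round(unname(sm$sd[c("g_il", "g_el", "g_et", "g_in", "g_en")]), 1),
               c(0.9, 1.2, 0.6, 0.1, 0.1))
  expect_equal(round(sm$sd[["g_it"]], 2), 0.24)
  # single-row table has zero std under the population convention
  one <- literature_table()[4, ]
  sm1 <- literature_summary(one, convention = "population")
  expect_equal(unname(sm1$sd), rep(0, 6))
})

test_that("conductivity ratio features behave as documented", {
  g <- t(as.matrix(mean_conductivities()[1:6]))
  rf <- ratio_features(g)
  expect_equal(rf[1, "g_il/g_el"], 1, ignore_attr = TRUE)
  expect_equal(rf[1, "g_il/g_it"], 10, ignore_attr = TRUE)
  expect_equal(ratio_features(3 * g), rf)
})
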