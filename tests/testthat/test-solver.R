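test_that("assembled operator conserves flux and reduces to the 7-point stencil", {
  mesh <- unit_cube_mesh(3)
  # isotropic unit tensor: hand-computed 7-point stencil oracle, h = 1/3:
  # off-diagonals -k*h to the 6 axis neighbours, diagonal 6*k*h
  A <- constant_tensor_operator(mesh, 1, 1, 1, 0)
  n1 <- 4
  centre <- 2 + n1 * 1 + n1^2 * 1 + 1  # node (2,2,2) 0-based -> interior
  row <- A[centre, ]
  h <- 1 / 3
  expect_equal(row[centre], 6 * h)
  nb <- centre + c(-1, 1, -n1, n1, -n1^2, n1^2)
  expect_equal(as.vector(row[nb]), rep(-h, 6))
  expect_equal(sum(abs(row[-c(centre, nb)])), 0)
  # discrete conservation: all row sums vanish for the natural-BC operator
  expect_lt(max(abs(Matrix::rowSums(A))), 1e-10 * max(abs(A)))
  # symmetry, also with a full (rotated) tensor
  Af <- constant_tensor_operator(mesh, 2, 1, 0.5, 0.6)
  expect_lt(max(abs(Af - Matrix::t(Af))), 1e-12)
  expect_lt(max(abs(Matrix::rowSums(Af))), 1e-10 * max(abs(Af)))
})

test_that("constant transmembrane potential produces a zero right-hand side", {
  mesh <- build_mesh("mini")
  cond <- mean_conductivities()
  sys <- assemble_bidomain(mesh, cond, 100, rep(7.3, mesh$n_nodes))
  expect_lt(max(abs(sys$b)), 1e-9)
})

test_that("manufactured solutions converge at second order", {
  # all-Dirichlet box, phi* = sin(pi x) sin(pi y) sin(pi z); the source is
  # moved to the right-hand side with lumped node volumes
  mms_err <- function(n, Mxx, Myy, Mzz, Mxy) {
    mesh <- unit_cube_mesh(n)
    A <- constant_tensor_operator(mesh, Mxx, Myy, Mzz, Mxy)
    nd <- mesh_nodes(mesh)
    phi_star <- sin(pi * nd$x) * sin(pi * nd$y) * sin(pi * nd$z)
    f <- pi^2 * (Mxx + Myy + Mzz) * phi_star -
      2 * Mxy * pi^2 * cos(pi * nd$x) * cos(pi * nd$y) * sin(pi * nd$z)
    h <- 1 / n
    interior <- nd$x > h / 2 & nd$x < 1 - h / 2 & nd$y > h / 2 &
      nd$y < 1 - h / 2 & nd$z > h / 2 & nd$z < 1 - h / 2
    b <- f * h^3
    sol <- Matrix::solve(A[interior, interior], b[interior])
    max(abs(as.vector(sol) - phi_star[interior]))
  }
  # diagonal anisotropic tensor
  e1 <- vapply(c(4, 8, 16), mms_err, numeric(1), 2, 1, 0.5, 0)
  order_d <- log2(e1[1:2] / e1[2:3])
  expect_true(all(order_d > 1.7 & order_d < 2.3))
  # full tensor with the fibre-rotation cross term
  e2 <- vapply(c(4, 8, 16), mms_err, numeric(1), 2, 1, 0.5, 0.6)
  order_f <- log2(e2[1:2] / e2[2:3])
  expect_true(all(order_f > 1.7 & order_f < 2.3))
})

test_that("zero source yields the zero potential everywhere", {
  mesh <- build_mesh("mini")
  cond <- mean_conductivities()
  sys <- assemble_bidomain(mesh, cond, 100, numeric(mesh$n_nodes))
  sol <- solve_bidomain(sys)
  expect_equal(max(abs(sol$phi)), 0)
})

test_that("solved EPDs inherit the point symmetry of the model", {
  e <- simulate_epd(mean_pars(), 0.3, build_mesh("mini"))
  v <- e$values
  vr <- v[rev(seq_len(nrow(v))), rev(seq_len(ncol(v)))]
  expect_lt(max(abs(v - vr)), 1e-7 * max(abs(v)))
  # the two outside minima (y > 0 and its mirror) have equal value
  up <- v; up[, e$y <= 0] <- Inf
  dn <- v; dn[, e$y >= 0] <- Inf
  expect_equal(min(up), min(dn), tolerance = 1e-7)
})

test_that("EPD extraction returns the epicardial slice with mesh dimensions", {
  mesh <- build_mesh("mini")
  cond <- mean_conductivities()
  sys <- assemble_bidomain(mesh, cond, 100, transmembrane_field(mesh, 0.4))
  sol <- solve_bidomain(sys)
  e <- extract_epd(sol)
  expect_equal(dim(e$values), c(mesh$nx + 1, mesh$ny + 1))
  expect_equal(e$x, mesh$x)
  expect_lt(sol$residual, 1e-8)
})

test_that("feature values converge under mesh refinement", {
  pars <- mean_pars()
  presets <- list(c(6, 6), c(8, 8), c(12, 12))
  vals <- t(vapply(presets, function(p) {
    m <- build_mesh(NULL, nxy_in = p[1], nxy_out = p[2],
                    nz_tissue = 10, nz_blood = 8)
    f <- extract_features(simulate_epd(pars, 0.6, m))
    c(f$cminV, f$cmaxV, f$ominV)
  }, numeric(3)))
  # successive differences shrink toward the resolved values
  d1 <- abs(vals[2, ] - vals[1, ])
  d2 <- abs(vals[3, ] - vals[2, ])
  expect_true(all(d2 < d1 + 0.02))
  expect_true(all(abs(vals[3, ] - vals[2, ]) < 0.1))
})

test_that("one-at-a-time parameter shifts reproduce the summary sign relations", {
  mesh <- build_mesh("small")
  rg <- default_ranges()
  run <- function(pars, depth) extract_features(simulate_epd(pars, depth, mesh))
  base <- mean_pars()
  # increasing g_in deepens the central depression (cminV decreases)
  lo <- base; lo[["g_in"]] <- rg$min[["g_in"]]
  hi <- base; hi[["g_in"]] <- rg$max[["g_in"]]
  expect_lt(run(hi, 0.1)$cminV, run(lo, 0.1)$cminV)
  # increasing g_en raises the central potential (cminV increases)
  lo <- base; lo[["g_en"]] <- rg$min[["g_en"]]
  hi <- base; hi[["g_en"]] <- rg$max[["g_en"]]
  expect_gt(run(hi, 0.1)$cminV, run(lo, 0.1)$cminV)
  # increasing fibre rotation rotates the pattern anticlockwise
  lo <- base; lo[["ROT"]] <- 60
  hi <- base; hi[["ROT"]] <- 140
  expect_gt(run(hi, 0.1)$ellipse_angle, run(lo, 0.1)$ellipse_angle)
  expect_gt(run(hi, 0.3)$angmin, run(lo, 0.3)$angmin)
})

test_that("deepening ischaemia walks the pattern through the three classes", {
  mesh <- build_mesh("small")
  pars <- mean_pars()
  types <- vapply(c(0.1, 0.3, 0.6), function(d)
    extract_features(simulate_epd(pars, d, mesh))$epd_type, character(1))
  expect_equal(types, c("depression_type1", "depression_type2", "elevation"))
})
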