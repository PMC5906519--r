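lhs_design <- function(n, d, seed) {
  latin_hypercube(n, parameter_ranges(data.frame(
    name = paste0("x", seq_len(d)), min = 0, mean = 0.5, max = 1)),
    seed = seed)$points
}

test_that("a linear response is absorbed by the linear mean", {
  X <- lhs_design(60, 4, 1)
  y <- 2 + 3 * X[, 1] - X[, 2]
  fit <- gp_fit(X, y, seed = 5)
  expect_true(fit$validation$pass)
  # interpolation at training points
  p <- predict(fit$model, X)
  expect_lt(max(abs(p$mean - y)), 1e-5)
  # held-out prediction essentially exact
  Xn <- lhs_design(30, 4, 2)
  expect_lt(max(abs(predict(fit$model, Xn)$mean - (2 + 3 * Xn[, 1] - Xn[, 2]))),
            1e-5)
})

test_that("a smooth nonlinear surrogate is emulated to a few percent", {
  sg <- make_surrogate(linear = c(1, 0.5, rep(0, 6)),
                       sinusoid = c(0, 0, 0.8, rep(0, 5)))
  X <- lhs_design(216, 8, 3)
  y <- sg$f(X)
  Xt <- lhs_design(50, 8, 4)
  fit <- gp_fit(X, y, seed = 6)
  rmse <- sqrt(mean((predict(fit$model, Xt)$mean - sg$f(Xt))^2))
  expect_lt(rmse, 0.05 * diff(range(y)))
  expect_true(fit$validation$pass)
})

test_that("Mahalanobis validation is calibrated against its reference distribution", {
  X <- lhs_design(40, 3, 7)
  y <- sin(2 * pi * X[, 1]) + X[, 2]^2
  m <- epduq:::.gp_train(X, y, seed = 1, estimate_nugget = FALSE)
  Xt <- lhs_design(8, 3, 8)
  # an emulator that interpolates the test data has D far below the
  # reference mean of 8 (exactly 0 in exact arithmetic; the ratio of
  # near-zero residuals to near-zero predictive variance is evaluated in
  # floating point)
  v0 <- mahalanobis_validate(m, X[1:8, , drop = FALSE], y[1:8])
  expect_lt(v0$D, 0.5)
  # residuals drawn from the predictive distribution itself: D falls within
  # 3 reference sd of the reference mean in nearly all replicates
  p <- predict(m, Xt, full_cov = TRUE)
  ev <- eigen(p$cov, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
  set.seed(42)
  inside <- vapply(1:200, function(i) {
    yt <- p$mean + as.vector(L %*% rnorm(8))
    mahalanobis_validate(m, Xt, yt)$pass
  }, logical(1))
  expect_gte(mean(inside), 0.95)
  # reference mean equals the held-out count (the 216/24 split anchor)
  X2 <- lhs_design(240, 8, 9)
  f2 <- gp_fit(X2, 2 * X2[, 1] + X2[, 2], train_fraction = 0.9, seed = 1)
  expect_equal(f2$validation$n_train, 216)
  expect_equal(f2$validation$ref_mean, 24)
})

test_that("main-effect curves recover known conditional expectations", {
  X <- lhs_design(120, 4, 11)
  # constant response: flat zero curve
  fitc <- epduq:::.gp_train(X, rep(2, 120) + 1e-9 * X[, 1], seed = 1)
  mec <- main_effect(fitc, 2)
  expect_lt(max(abs(mec$effect)), 1e-4)
  # additive response: the curve for x_w is f's own w-term, centred
  y <- 3 * X[, 1] + sin(2 * pi * X[, 2])
  fit <- gp_fit(X, y, seed = 2)
  me2 <- main_effect(fit$model, 2, others_variance = 0.04)
  # E[sin(2 pi U)] under N(.5, .04) is exactly 0, so the centred curve is
  # f's own second term
  expect_lt(max(abs(me2$effect - sin(2 * pi * me2$x))), 0.08)
  # multiplicative response: E{f | x_1} = 0.5 x_1 - 0.25 after centring
  y2 <- X[, 1] * X[, 2]
  fit2 <- gp_fit(X, y2, seed = 3)
  me1 <- main_effect(fit2$model, 1, others_variance = 0.04)
  expect_lt(max(abs(me1$effect - (0.5 * me1$x - 0.25))), 0.01)
})

test_that("sensitivity indices recover analytic variance decompositions", {
  X <- lhs_design(120, 4, 13)
  fit1 <- gp_fit(X, X[, 1] + 0.001 * X[, 2], seed = 1)
  si1 <- sensitivity_indices(fit1$model)
  expect_equal(unname(si1$indices[1]), 1, tolerance = 0.02)
  expect_true(all(si1$indices[-1] < 0.02))
  # f = 3 x1 + x2: indices 9/10 and 1/10
  fit2 <- gp_fit(X, 3 * X[, 1] + X[, 2], seed = 2)
  si2 <- sensitivity_indices(fit2$model)
  expect_equal(unname(si2$indices[1:2]), c(0.9, 0.1), tolerance = 0.02)
  expect_equal(si2$sum, 1, tolerance = 0.02)
  # indices lie in [0,1] and rescaling y leaves them unchanged
  fit3 <- gp_fit(X, sin(2 * pi * X[, 1]) + X[, 2] * X[, 3], seed = 3)
  si3 <- sensitivity_indices(fit3$model)
  expect_true(all(si3$indices > -0.01 & si3$indices < 1.01))
  fit3b <- gp_fit(X, 5 * (sin(2 * pi * X[, 1]) + X[, 2] * X[, 3]) - 2, seed = 3)
  si3b <- sensitivity_indices(fit3b$model)
  expect_equal(si3b$indices, si3$indices, tolerance = 0.03)
})

test_that("surrogates with prescribed indices are recovered at design size 216", {
  sg <- make_surrogate(linear = c(3, 1, rep(0, 6)),
                       sinusoid = c(0, 0, 1.2, rep(0, 5)))
  X <- lhs_design(216, 8, 17)
  fit <- gp_fit(X, sg$f(X), seed = 4)
  si <- sensitivity_indices(fit$model, others_variance = 0.02)
  expect_equal(unname(si$indices), unname(sg$indices), tolerance = 0.05)
  expect_equal(si$sum, 1, tolerance = 0.05)
})
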