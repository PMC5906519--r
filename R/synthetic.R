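# Test harness generators: cheap surrogate response functions with
# analytically known sensitivity structure, synthetic EPD fields with known
# extrema and pattern class, and a fast mock simulator mimicking the
# qualitative solver behaviours (pattern transition with depth,
# anticlockwise rotation with fibre rotation, deepening with g_in).

#' Surrogate response function with analytic sensitivity indices
#'
#' Builds f(u) = sum_d a_d u_d + sum_d s_d sin(2 pi u_d)
#' + sum_(j,k) b_jk (u_j - mu)(u_k - mu) on the unit cube, together with
#' its exact main-effect sensitivity indices under independent
#' N(mu, v) inputs.  The sinusoid and interaction terms let tests exercise
#' non-linearity and index sums below 1.
#'
#' @param linear length-d vector of linear coefficients a_d
#' @param sinusoid length-d vector of sinusoid amplitudes s_d (default 0)
#' @param interactions 3-column matrix (j, k, b_jk) of pairwise
#'   interaction terms (default none)
#' @param mu,v input distribution used for the analytic indices
#'   (defaults 0.5 and 0.02)
#' @param noise_sd standard deviation of optional additive noise
#' @param seed seed used when \code{noise_sd > 0}
#' @return A \code{surrogate}: list with \code{f} (vectorized over matrix
#'   rows), \code{indices} (analytic main-effect indices; all NA when the
#'   total variance is zero), \code{total_variance}, \code{d}.
#' @export
make_surrogate <- function(linear, sinusoid = NULL, interactions = NULL,
                           mu = 0.5, v = 0.02, noise_sd = 0, seed = 1) {
  d <- length(linear)
  if (is.null(sinusoid)) sinusoid <- numeric(d)
  stopifnot(length(sinusoid) == d, all(is.finite(c(linear, sinusoid))))
  if (!is.null(interactions)) {
    interactions <- matrix(interactions, ncol = 3)
    stopifnot(all(interactions[, 1:2] >= 1), all(interactions[, 1:2] <= d))
  }
  a <- linear; s <- sinusoid
  f <- function(U) {
    U <- if (is.matrix(U)) U else matrix(U, nrow = 1)
    out <- as.vector(U %*% a) + as.vector(sin(2 * pi * U) %*% s)
    if (!is.null(interactions))
      for (r in seq_len(nrow(interactions)))
        out <- out + interactions[r, 3] *
          (U[, interactions[r, 1]] - mu) * (U[, interactions[r, 2]] - mu)
    if (noise_sd > 0) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed + nrow(U))
      out <- out + rnorm(length(out), 0, noise_sd)
    }
    out
  }
  # analytic one-dimensional main-effect variances under U_d ~ N(mu, v):
  #   Var(a U + s sin(2 pi U))
  #     = a^2 v + s^2 (1 - cos(4 pi mu) e^{-8 pi^2 v}) / 2
  #       - s^2 sin^2(2 pi mu) e^{-4 pi^2 v}
  #       + 2 a s Cov(U, sin 2 pi U),   Cov = 2 pi v cos(2 pi mu) e^{-2 pi^2 v}
  Es <- sin(2 * pi * mu) * exp(-2 * pi^2 * v)
  Vs <- (1 - cos(4 * pi * mu) * exp(-8 * pi^2 * v)) / 2 - Es^2
  Cus <- 2 * pi * v * cos(2 * pi * mu) * exp(-2 * pi^2 * v)
  Vd <- a^2 * v + s^2 * Vs + 2 * a * s * Cus
  Vint <- if (is.null(interactions)) 0 else sum(interactions[, 3]^2) * v^2
  total <- sum(Vd) + Vint + noise_sd^2
  indices <- if (total > 0) Vd / total else rep(NA_real_, d)
  structure(list(f = f, indices = indices, total_variance = total, d = d),
            class = "surrogate")
}

#' Synthetic EPD built from Gaussian wells and peaks
#'
#' Superposes anisotropic, rotated Gaussian components on a uniform grid
#' over [-8, 8]^2, and computes ground-truth features by dense brute force
#' on a fine oracle grid (0.05 cm), independent of [extract_features()].
#'
#' @param components data frame with columns \code{x0}, \code{y0}
#'   (centre, cm), \code{amp} (depth < 0 or height > 0, mV), \code{sx},
#'   \code{sy} (widths, cm), \code{theta} (orientation, degrees)
#' @param n grid nodes per axis for the returned EPD (default 81)
#' @param oracle_h oracle grid spacing [cm]
#' @return List with \code{epd} (an [epd]) and \code{truth} (brute-force
#'   cminV, cmaxV, ominV, angmin location/angle, epd_type).
#' @export
make_synthetic_epd <- function(components, n = 81, oracle_h = 0.05) {
  field <- function(x, y) {
    X <- outer(x, rep(1, length(y))); Y <- outer(rep(1, length(x)), y)
    v <- matrix(0, length(x), length(y))
    for (r in seq_len(nrow(components))) {
      cc <- components[r, ]
      th <- cc$theta * pi / 180
      dx <- X - cc$x0; dy <- Y - cc$y0
      u1 <- cos(th) * dx + sin(th) * dy
      u2 <- -sin(th) * dx + cos(th) * dy
      v <- v + cc$amp * exp(-(u1^2 / (2 * cc$sx^2) + u2^2 / (2 * cc$sy^2)))
    }
    v
  }
  xg <- seq(-8, 8, length.out = n)
  e <- epd(xg, xg, field(xg, xg))
  xo <- seq(-8, 8, by = oracle_h)
  vo <- field(xo, xo)
  mo <- outer(abs(xo) <= 2, abs(xo) <= 2, `&`)
  cminV <- min(vo[mo]); cmaxV <- max(vo[mo]); ominV <- min(vo[!mo])
  out_up <- !mo & outer(rep(TRUE, length(xo)), xo > 0)
  angmin <- NA_real_
  if (any(out_up)) {
    vv <- vo; vv[!out_up] <- Inf
    k <- arrayInd(which.min(vv), dim(vv))
    angmin <- (atan2(xo[k[2]], xo[k[1]]) * 180 / pi) %% 180
  }
  truth <- list(cminV = cminV, cmaxV = cmaxV, ominV = ominV,
                angmin = angmin,
                epd_type = classify_epd(cminV, cmaxV, ominV))
  list(epd = e, truth = truth)
}

#' Fast mock EPD simulator with the qualitative solver behaviours
#'
#' Analytic stand-in for the PDE solver, for pipeline and unit tests only
#' (not calibrated to physical magnitudes).  Constructed hooks: the pattern
#' class walks depression type 1 -> type 2 -> elevation as the ischaemic
#' depth rises; the outside-extremum angle increases linearly with fibre
#' rotation and decreases with depth; raising g_in deepens (and g_en
#' shallows) the central potential.
#'
#' @param pars named vector with the eight physical inputs (Table-2 box)
#' @param depth ischaemic depth fraction
#' @param n grid nodes per axis
#' @param ranges parameter ranges used to normalize the inputs
#' @return An [epd].
#' @export
mock_simulator <- function(pars, depth, n = 65, ranges = default_ranges()) {
  u <- normalize_inputs(pars[.INPUTS], ranges)
  if (any(u < -1e-9 | u > 1 + 1e-9)) stop("inputs outside the sampling box")
  # central component: negative well for shallow ischaemia, crossing to a
  # positive bump (ST elevation) as depth rises; modulated by g_in / g_en
  camp <- -1.5 + 3.0 * depth - 0.5 * u[["g_in"]] + 0.35 * u[["g_en"]]
  # flanking wells: deepen with depth and g_in
  oamp <- -(0.30 + 1.9 * depth + 0.3 * u[["g_in"]])
  ang <- 50 + 50 * u[["ROT"]] - 35 * (depth - 0.55)
  th <- ang * pi / 180
  ell <- 12 + 55 * u[["ROT"]]
  comp <- data.frame(
    x0 = c(0, 3.2 * cos(th), -3.2 * cos(th)),
    y0 = c(0, 3.2 * sin(th), -3.2 * sin(th)),
    amp = c(camp, oamp, oamp),
    sx = c(2.2, 1.1, 1.1), sy = c(1.2, 1.1, 1.1),
    theta = c(ell, 0, 0))
  make_synthetic_epd(comp, n = n, oracle_h = 0.5)$epd
}
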