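# Geometry, graded hexahedral mesh, transmural fibre field, rotated
# conductivity tensors, and the analytic ischaemic transmembrane source.
#
# Coordinates: x, y in [-8, 8] cm; tissue z in [0, 1] cm with the epicardium
# at z = 0 and the endocardium at z = 1; blood from z = 1 to z = 26 cm.
# The ischaemic footprint is the central 4 cm x 4 cm square (|x|,|y| <= 2).

# geometric progression of n cell sizes over length L with growth ratio r
.geo_sizes <- function(L, n, r) {
  if (abs(r - 1) < 1e-12) return(rep(L / n, n))
  h0 <- L * (r - 1) / (r^n - 1)
  h0 * r^(0:(n - 1))
}

# one axis of the x/y grid on [-8, 8]: cells clustered at the ischaemic
# border +/-2 from both sides; n_in cells per [0,2]-type segment, n_out per
# [2,8]-type segment (total 2*(n_in + n_out) cells), node exactly at +/-2, 0
.graded_axis <- function(n_in, n_out, r_in = 1.2, r_out = 1.35) {
  h_in <- .geo_sizes(2, n_in, 1 / r_in)    # [0,2]: shrinking toward 2
  h_out <- .geo_sizes(6, n_out, r_out)     # [2,8]: growing away from 2
  right <- cumsum(c(h_in, h_out))
  right[n_in] <- 2                         # pin the border node exactly
  right[n_in + n_out] <- 8
  sort(unique(c(-right, 0, right)))
}

# blood z spacing: geometric growth from the tissue spacing down to z = 26
.blood_coords <- function(h_tissue, n_blood) {
  f <- function(r) h_tissue * sum(r^(1:n_blood)) - 25
  r <- uniroot(f, c(1 + 1e-9, 10), tol = 1e-12)$root
  h <- h_tissue * r^(1:n_blood)
  h <- h * (25 / sum(h))          # land exactly on z = 26
  1 + cumsum(h)
}

#' Build a graded hexahedral mesh of the tissue slab plus blood mass
#'
#' Tensor-product mesh of the 16 x 16 x 1 cm tissue slab and the 25 cm
#' blood mass beneath it (z from 0 at the epicardium to 26 cm at the bottom
#' of the blood).  Nodes in x and y are clustered around the borders of the
#' ischaemic footprint (x, y = +/-2 cm); tissue z spacing is uniform and the
#' blood z spacing is geometrically stretched.
#'
#' @param preset one of \code{"mini"}, \code{"small"}, \code{"coarse"},
#'   \code{"full"}; or \code{NULL} to use the explicit cell counts
#' @param nxy_in,nxy_out cells per graded x/y segment (inside [0,2] /
#'   outside [2,8] per half-axis); total x cells = 2*(nxy_in + nxy_out)
#' @param nz_tissue uniform cells through the 1 cm tissue wall
#' @param nz_blood geometrically stretched cells through the blood
#' @return A \code{mesh} object: node coordinate vectors \code{x}, \code{y},
#'   \code{z}; cell counts; \code{nz_tissue}; node/cell totals.
#' @export
build_mesh <- function(preset = "coarse", nxy_in = NULL, nxy_out = NULL,
                       nz_tissue = NULL, nz_blood = NULL) {
  if (!is.null(preset)) {
    p <- switch(preset,
      mini   = c(4, 4, 10, 6),
      small  = c(6, 6, 10, 8),
      medium = c(8, 8, 10, 16),
      coarse = c(8, 8, 20, 12),
      full   = c(15, 15, 50, 50),
      stop("unknown mesh preset: ", preset))
    nxy_in <- p[1]; nxy_out <- p[2]; nz_tissue <- p[3]; nz_blood <- p[4]
  }
  x <- .graded_axis(nxy_in, nxy_out)
  z_t <- seq(0, 1, length.out = nz_tissue + 1)
  z <- c(z_t, .blood_coords(1 / nz_tissue, nz_blood))
  if (any(diff(x) <= 0) || any(diff(z) <= 0)) stop("mesh coordinates not increasing")
  m <- list(x = x, y = x, z = z,
            nx = length(x) - 1, ny = length(x) - 1, nz = length(z) - 1,
            nz_tissue = nz_tissue,
            n_nodes = length(x)^2 * length(z),
            n_cells = (length(x) - 1)^2 * (length(z) - 1),
            preset = if (is.null(preset)) "custom" else preset)
  structure(m, class = "mesh")
}

#' @export
print.mesh <- function(x, ...) {
  cat(sprintf("mesh ('%s'): %d x %d x %d cells (%d tissue z-layers), %d nodes\n",
              x$preset, x$nx, x$ny, x$nz, x$nz_tissue, x$n_nodes))
  invisible(x)
}

#' Ischaemic source-profile factor
#'
#' One-dimensional profile of the transmembrane-potential source: 1 at the
#' centre of the ischaemic region, 1/2 at the border |t| = a, decaying
#' exponentially outside, with border-zone steepness lambda.  Evaluated in a
#' numerically stable form (the naive sinh/cosh expressions overflow for
#' a/lambda of a few hundred).
#'
#' @param t coordinate [cm] (vectorized)
#' @param a half-width of the ischaemic region [cm]
#' @param lambda border-zone steepness [cm]
#' @return Value(s) in [0, 1].
#' @export
psi <- function(t, a, lambda = 0.01) {
  if (a <= 0 || lambda <= 0) stop("a and lambda must be positive")
  t <- abs(t)
  den <- 1 - exp(-a / lambda)
  inner <- (1 - (exp((t - a) / lambda) + exp(-(t + a) / lambda)) / 2) / den
  outer <- ((exp((a - t) / lambda) - exp(-(a + t) / lambda)) / 2) / den
  ifelse(t <= a, inner, outer)
}

#' Transmembrane potential field of subendocardial ischaemia
#'
#' phi_m(x, y, z) = dphi_p * Psi(x) Psi(y) Psi(1 - z): a separable plateau
#' of depth dphi_p over the ischaemic region (footprint |x|,|y| <= a_xy cm,
#' extending from the endocardium z = 1 down to z = 1 - depth), with sharp
#' border zones.  Returns the field on all mesh nodes (zero in the blood).
#'
#' @param mesh a \code{mesh}
#' @param depth ischaemic depth as a fraction of wall thickness, in (0, 1)
#' @param dphi_p plateau potential difference [mV], default -30
#' @param lambda border-zone steepness [cm], default 0.01
#' @param a_xy footprint half-width [cm], default 2
#' @return Numeric vector over mesh nodes (x fastest, then y, then z).
#' @export
transmembrane_field <- function(mesh, depth, dphi_p = -30, lambda = 0.01,
                                a_xy = 2) {
  stopifnot(depth > 0, depth < 1)
  px <- psi(mesh$x, a_xy, lambda)
  py <- psi(mesh$y, a_xy, lambda)
  pz <- numeric(length(mesh$z))
  it <- mesh$z <= 1 + 1e-12
  pz[it] <- psi(1 - mesh$z[it], depth, lambda)
  dphi_p * as.vector(outer(outer(px, py), pz))
}

#' Transmural fibre angle
#'
#' Fibres lie in the x-y plane, aligned with the x-axis on the epicardium
#' (z = 0) and rotating linearly with depth to ROT degrees at the
#' endocardium (z = 1 cm).
#'
#' @param z depth in the tissue [cm], in [0, 1]
#' @param ROT total transmural rotation [degrees]
#' @return Fibre angle(s) in degrees.
#' @export
fibre_angle <- function(z, ROT) {
  if (any(z < -1e-12 | z > 1 + 1e-12)) stop("z outside the tissue wall [0, 1] cm")
  ROT * z
}

#' Anisotropic bidomain conductivity tensor
#'
#' M_p = A G_p A^T with G_p = diag(g_pl, g_pt, g_pn) and A the rotation by
#' the fibre angle about the z-axis (sheets parallel to the epicardium).
#'
#' @param set a \code{conductivity_set}
#' @param theta fibre angle [degrees]
#' @param space \code{"i"} (intracellular) or \code{"e"} (extracellular)
#' @return Symmetric 3 x 3 tensor [mS/cm].
#' @export
conductivity_tensor <- function(set, theta, space = c("i", "e")) {
  space <- match.arg(space)
  g <- c(set[[paste0("g_", space, "l")]],
         set[[paste0("g_", space, "t")]],
         set[[paste0("g_", space, "n")]])
  th <- theta * pi / 180
  A <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  A %*% diag(g) %*% t(A)
}
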