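# Reduction of an epicardial potential distribution to scalar features and
# classification into ST depression (type 1 / type 2) or ST elevation.

#' Construct an epicardial potential distribution
#'
#' A 2-D potential field on the epicardial (z = 0) node grid, together with
#' the mask of the central ischaemic footprint |x| <= 2, |y| <= 2 cm.
#'
#' @param x,y node coordinates [cm]
#' @param values matrix of potentials [mV], \code{length(x)} rows by
#'   \code{length(y)} columns
#' @param footprint half-width of the central footprint [cm]
#' @return An object of class \code{epd}.
#' @export
epd <- function(x, y, values, footprint = 2) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(x), ncol(values) == length(y))
  if (any(!is.finite(values))) stop("EPD values must be finite")
  mask <- outer(abs(x) <= footprint + 1e-9, abs(y) <= footprint + 1e-9, `&`)
  structure(list(x = x, y = y, values = values, mask = mask,
                 footprint = footprint),
            class = "epd")
}

#' @export
print.epd <- function(x, ...) {
  cat(sprintf("epd: %d x %d grid, range [%.3f, %.3f] mV\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

# bilinear resampling of an EPD onto a uniform grid (makes region-based
# features independent of the mesh grading)
.interp_epd <- function(e, h = 0.1) {
  xo <- seq(min(e$x), max(e$x), by = h)
  yo <- seq(min(e$y), max(e$y), by = h)
  ix <- pmin(pmax(findInterval(xo, e$x), 1), length(e$x) - 1)
  iy <- pmin(pmax(findInterval(yo, e$y), 1), length(e$y) - 1)
  tx <- (xo - e$x[ix]) / (e$x[ix + 1] - e$x[ix])
  ty <- (yo - e$y[iy]) / (e$y[iy + 1] - e$y[iy])
  v <- e$values
  v00 <- v[ix, iy]; v10 <- v[ix + 1, iy]
  v01 <- v[ix, iy + 1]; v11 <- v[ix + 1, iy + 1]
  wx <- matrix(tx, length(xo), length(yo))
  wy <- matrix(ty, length(xo), length(yo), byrow = TRUE)
  vals <- (1 - wx) * (1 - wy) * v00 + wx * (1 - wy) * v10 +
    (1 - wx) * wy * v01 + wx * wy * v11
  list(x = xo, y = yo, values = vals)
}

# strict local extrema over the 8-neighbour stencil (interior nodes only)
.local_extrema <- function(v, minimum = TRUE) {
  n <- nrow(v); m <- ncol(v)
  if (n < 3 || m < 3) return(matrix(numeric(0), 0, 2))
  core <- v[2:(n - 1), 2:(m - 1)]
  strict <- matrix(TRUE, n - 2, m - 2)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- v[2:(n - 1) + di, 2:(m - 1) + dj]
    strict <- strict & (if (minimum) core < nb else core > nb)
  }
  which(strict, arr.ind = TRUE) + 1L
}

# sub-grid refinement of an extremum location: least-squares quadratic
# surface over the 3x3 neighbourhood (handles graded grids and cross
# curvature), stationary point clipped to the neighbourhood
.refine_extremum <- function(e, i, j) {
  x <- e$x; y <- e$y; v <- e$values
  if (i <= 1 || i >= nrow(v) || j <= 1 || j >= ncol(v))
    return(c(x[i], y[j]))
  xs <- x[(i - 1):(i + 1)] - x[i]
  ys <- y[(j - 1):(j + 1)] - y[j]
  X <- rep(xs, 3); Y <- rep(ys, each = 3)
  f <- as.vector(v[(i - 1):(i + 1), (j - 1):(j + 1)])
  B <- cbind(1, X, Y, X^2, Y^2, X * Y)
  cf <- tryCatch(qr.solve(B, f), error = function(e) NULL)
  if (is.null(cf)) return(c(x[i], y[j]))
  Hm <- matrix(c(2 * cf[4], cf[6], cf[6], 2 * cf[5]), 2, 2)
  if (abs(det(Hm)) < 1e-12) return(c(x[i], y[j]))
  p <- -solve(Hm, cf[2:3])
  p <- c(min(max(p[1], xs[1]), xs[3]), min(max(p[2], ys[1]), ys[3]))
  c(x[i] + p[1], y[j] + p[2])
}

# angle from origin to (x, y), degrees reduced to [0, 180)
.angle_deg <- function(x, y) {
  a <- atan2(y, x) * 180 / pi
  a <- a %% 180
  if (a >= 180 - 1e-9) a <- 0
  a
}

#' Angle of an EPD extremum in the upper half-plane
#'
#' Finds the requested extremum (local over the 8-neighbour stencil, with
#' sub-grid quadratic refinement of its location) among nodes with y > 0,
#' optionally restricted to outside the central footprint, and returns the
#' angle from the origin to it, measured from the +x axis in [0, 180)
#' degrees.  Ties between equally deep extrema are broken by smallest angle.
#'
#' Candidate extrema are strict local extrema of the full field over the
#' 8-neighbour stencil (which excludes flat boundary artefacts).  For
#' \code{region = "outside"} a candidate qualifies if its refined location
#' lies outside the central footprint or within \code{margin} of its
#' boundary: the outside minima of tripolar and elevation patterns sit on
#' the lateral boundaries of the central region and may straddle the mask
#' line by a node.
#'
#' @param e an [epd]
#' @param which \code{"min"} or \code{"max"}
#' @param region \code{"outside"} (outside the central footprint, with the
#'   boundary margin above) or \code{"anywhere"}
#' @param margin boundary tolerance [cm] for \code{region = "outside"}
#' @return Angle in degrees, or \code{NA_real_} if no qualifying extremum
#'   exists (an undefined-feature signal, not an error).
#' @export
extremum_angle <- function(e, which = c("min", "max"),
                           region = c("outside", "anywhere"),
                           margin = 0.5) {
  which <- match.arg(which); region <- match.arg(region)
  v <- if (which == "min") e$values else -e$values
  cand <- .local_extrema(v, minimum = TRUE)
  if (nrow(cand) == 0) return(NA_real_)
  fp <- if (is.null(e$footprint)) 2 else e$footprint
  keep <- logical(nrow(cand)); loc <- matrix(0, nrow(cand), 2)
  for (k in seq_len(nrow(cand))) {
    p <- .refine_extremum(e, cand[k, 1], cand[k, 2])
    loc[k, ] <- p
    keep[k] <- p[2] > 1e-9 &&
      (region == "anywhere" || max(abs(p)) > fp - margin)
  }
  if (!any(keep)) return(NA_real_)
  vals <- v[cand[keep, , drop = FALSE]]
  loc <- loc[keep, , drop = FALSE]
  best <- which(vals == min(vals))
  angs <- vapply(best, function(k) .angle_deg(loc[k, 1], loc[k, 2]),
                 numeric(1))
  min(angs)
}

#' Orientation of the ST-depression pattern
#'
#' Fits the principal axis of the region deeper than a fractional contour
#' between the field's background level (its median, which makes the
#' feature invariant under constant potential shifts) and the central
#' minimum: \{phi <= ref + level * (cminV - ref)\}, requiring
#' cminV < ref.  The EPD is first resampled bilinearly onto a uniform fine
#' grid so the region is independent of the mesh grading; the coordinate
#' covariance of the region's points is then computed and the angle of its
#' principal eigenvector to the +x axis, in [0, 180) degrees, is returned.
#' The eigenvalue ratio is attached as attribute \code{"axis_ratio"}; a
#' ratio near 1 marks a degenerate (near-circular) pattern.
#'
#' @param e an [epd]
#' @param level contour level as a fraction of the background-to-minimum
#'   drop (default 0.5)
#' @param h resampling grid spacing [cm]
#' @return Angle in degrees, or \code{NA_real_} when the region is empty.
#' @export
ellipse_angle <- function(e, level = 0.5, h = 0.1) {
  ref <- median(e$values)
  cmin <- min(e$values[e$mask])
  if (cmin >= ref) return(NA_real_)
  u <- .interp_epd(e, h)
  sel <- u$values <= ref + level * (cmin - ref)
  if (!any(sel)) return(NA_real_)
  X <- outer(u$x, rep(1, length(u$y)))[sel]
  Y <- outer(rep(1, length(u$x)), u$y)[sel]
  mx <- mean(X); my <- mean(Y)
  C <- matrix(c(mean((X - mx)^2), mean((X - mx) * (Y - my)),
                mean((X - mx) * (Y - my)), mean((Y - my)^2)), 2, 2)
  ev <- eigen(C, symmetric = TRUE)
  ang <- .angle_deg(ev$vectors[1, 1], ev$vectors[2, 1])
  ratio <- if (ev$values[2] > 0) ev$values[1] / ev$values[2] else Inf
  structure(ang, axis_ratio = ratio)
}

#' Classify an EPD from its potential features
#'
#' ST elevation iff cmaxV > 0; otherwise ST depression type 2 iff
#' ominV < cminV, else type 1 (cminV <= ominV < 0).
#'
#' @param cminV,cmaxV central minimum/maximum [mV]
#' @param ominV outside minimum [mV]
#' @return One of \code{"elevation"}, \code{"depression_type2"},
#'   \code{"depression_type1"}.
#' @export
classify_epd <- function(cminV, cmaxV, ominV) {
  if (cmaxV > 0) "elevation"
  else if (ominV < cminV) "depression_type2"
  else "depression_type1"
}

#' Extract the scalar features of an EPD
#'
#' cminV/cmaxV are the minimum/maximum over the central footprint
#' (|x|, |y| <= 2 cm), ominV the minimum over all other nodes; the pattern
#' class follows [classify_epd()]; ellipse_angle, angmin and angmax are the
#' orientation features (NA where undefined).
#'
#' @param e an [epd]
#' @return A \code{feature_set}: list with cminV, cmaxV, ominV,
#'   ellipse_angle, angmin, angmax, epd_type.
#' @export
extract_features <- function(e) {
  if (!any(e$mask) || all(e$mask)) stop("geometry error: footprint mask degenerate")
  cminV <- min(e$values[e$mask])
  cmaxV <- max(e$values[e$mask])
  ominV <- min(e$values[!e$mask])
  type <- classify_epd(cminV, cmaxV, ominV)
  structure(list(
    cminV = cminV, cmaxV = cmaxV, ominV = ominV,
    ellipse_angle = as.numeric(ellipse_angle(e)),
    angmin = extremum_angle(e, "min", "outside"),
    angmax = extremum_angle(e, "max", "anywhere"),
    epd_type = type), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set [%s]: cminV %.3f, cmaxV %.3f, ominV %.3f mV\n",
              x$epd_type, x$cminV, x$cmaxV, x$ominV))
  cat(sprintf("  ellipse %.1f deg, angmin %.1f deg, angmax %.1f deg\n",
              x$ellipse_angle, x$angmin, x$angmax))
  invisible(x)
}

#' Feature table for a set of EPDs
#'
#' @param epds list of [epd] objects
#' @return Data frame with one row per EPD (potentials, angles, class).
#' @export
feature_table <- function(epds) {
  rows <- lapply(epds, function(e) {
    f <- extract_features(e)
    data.frame(cminV = f$cminV, cmaxV = f$cmaxV, ominV = f$ominV,
               ellipse_angle = f$ellipse_angle, angmin = f$angmin,
               angmax = f$angmax, epd_type = f$epd_type,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
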