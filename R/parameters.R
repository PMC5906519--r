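#' @importFrom stats optim sd var cor rnorm runif dnorm median setNames uniroot
#' @importFrom utils read.csv head
NULL

# Canonical ordering of the eight varied model inputs.
.INPUTS <- c("ROT", "g_b", "g_il", "g_el", "g_it", "g_et", "g_in", "g_en")
.CONDUCTIVITIES <- c("g_il", "g_el", "g_it", "g_et", "g_in", "g_en")

#' The eight varied model inputs, in canonical order
#'
#' Fibre rotation (degrees) followed by blood conductivity and the six
#' bidomain conductivities (mS/cm).
#' @return Character vector of input names.
#' @export
input_names <- function() .INPUTS

#' Construct a conductivity set
#'
#' Bundles the six bidomain conductivities (intracellular/extracellular x
#' longitudinal/transverse/normal) and the blood conductivity, all in mS/cm.
#'
#' @param g_il,g_el,g_it,g_et,g_in,g_en bidomain conductivities [mS/cm]
#' @param g_b blood conductivity [mS/cm]
#' @return An object of class \code{conductivity_set} (named numeric vector).
#' @export
conductivity_set <- function(g_il, g_el, g_it, g_et, g_in, g_en, g_b = 6.5) {
  g <- c(g_il = g_il, g_el = g_el, g_it = g_it, g_et = g_et,
         g_in = g_in, g_en = g_en, g_b = g_b)
  if (any(!is.finite(g)) || any(g <= 0))
    stop("all conductivities must be finite and strictly positive")
  structure(g, class = "conductivity_set")
}

#' Conductivity set at the central (mean) parameter values
#' @param ranges a \code{parameter_ranges} object; defaults to [default_ranges()]
#' @return A \code{conductivity_set} at the range means.
#' @export
mean_conductivities <- function(ranges = default_ranges()) {
  m <- ranges$mean
  conductivity_set(m[["g_il"]], m[["g_el"]], m[["g_it"]], m[["g_et"]],
                   m[["g_in"]], m[["g_en"]], g_b = m[["g_b"]])
}

#' Default uncertainty ranges for the eight varied inputs
#'
#' Returns minimum/mean/maximum for fibre rotation, blood conductivity and
#' the six bidomain conductivities.  Conductivity ranges are mean +/- 50%.
#'
#' @return A \code{parameter_ranges} object: data frame with columns
#'   \code{name}, \code{min}, \code{mean}, \code{max} plus named-vector
#'   accessors \code{$min}, \code{$mean}, \code{$max}.
#' @export
default_ranges <- function() {
  path <- system.file("extdata", "table2_ranges.csv", package = "epduq")
  df <- read.csv(path, stringsAsFactors = FALSE)
  parameter_ranges(df)
}

#' Construct parameter ranges from a min/mean/max table
#' @param df data frame with columns name, min, mean, max
#' @return A \code{parameter_ranges} object.
#' @export
parameter_ranges <- function(df) {
  stopifnot(all(c("name", "min", "mean", "max") %in% names(df)))
  if (any(df$min >= df$mean) || any(df$mean >= df$max))
    stop("ranges must satisfy min < mean < max")
  if (max(abs(df$mean - (df$min + df$max) / 2)) > 1e-9 * max(df$max))
    stop("ranges must be symmetric: mean = (min + max)/2")
  obj <- list(table = df,
              min = setNames(df$min, df$name),
              mean = setNames(df$mean, df$name),
              max = setNames(df$max, df$name))
  structure(obj, class = "parameter_ranges")
}

#' @export
print.parameter_ranges <- function(x, ...) {
  cat("parameter_ranges over", nrow(x$table), "inputs\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Latin hypercube design on the unit cube
#'
#' Plain stratified-random Latin hypercube: for every dimension exactly one
#' point falls in each of the n equal-width strata of [0,1].
#'
#' @param n number of design points (>= 2)
#' @param ranges a \code{parameter_ranges} object giving the dimensions and
#'   their physical ranges
#' @param seed integer seed; the design is reproducible under a fixed seed
#' @return A \code{design_matrix}: list with \code{points} (n x d matrix in
#'   [0,1], columns named by input), \code{ranges}, \code{seed}.
#' @export
latin_hypercube <- function(n, ranges = default_ranges(), seed = 1L) {
  if (n < 2) stop("invalid design: n must be >= 2")
  d <- nrow(ranges$table)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pts <- lhs::randomLHS(n, d)
  colnames(pts) <- ranges$table$name
  structure(list(points = pts, ranges = ranges, seed = as.integer(seed)),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("design_matrix:", nrow(x$points), "points x", ncol(x$points),
      "inputs (seed", x$seed, ")\n")
  invisible(x)
}

#' Map unit-interval coordinates to physical parameter values
#'
#' Linear map u -> min + u * (max - min) per dimension; u = 0.5 maps to the
#' range mean.
#'
#' @param u numeric vector (or matrix with named columns) in [0,1]
#' @param ranges a \code{parameter_ranges}; names of \code{u} (or its
#'   columns) select the dimensions
#' @return Physical values with the same shape and names as \code{u}.
#' @export
denormalize <- function(u, ranges = default_ranges()) {
  if (any(u < 0 | u > 1)) stop("coordinates must lie in [0, 1]")
  nm <- if (is.matrix(u)) colnames(u) else names(u)
  if (is.null(nm)) stop("u must carry input names")
  lo <- ranges$min[nm]; hi <- ranges$max[nm]
  if (is.matrix(u)) sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
  else lo + u * (hi - lo)
}

#' Inverse of [denormalize()]
#' @param x physical values (vector or matrix with names as in
#'   [denormalize()])
#' @param ranges a \code{parameter_ranges}
#' @return Unit-interval coordinates.
#' @export
normalize_inputs <- function(x, ranges = default_ranges()) {
  nm <- if (is.matrix(x)) colnames(x) else names(x)
  if (is.null(nm)) stop("x must carry input names")
  lo <- ranges$min[nm]; hi <- ranges$max[nm]
  if (is.matrix(x)) sweep(sweep(x, 2, lo, "-"), 2, hi - lo, "/")
  else (x - lo) / (hi - lo)
}

#' Bulk conductivity ratio between two tissue directions
#'
#' g_A/g_B = (g_iA + g_eA) / (g_iB + g_eB) for directions in {l, t, n}.
#'
#' @param set a \code{conductivity_set}
#' @param A,B direction labels, one of \code{"l"}, \code{"t"}, \code{"n"}
#' @return The bulk ratio (dimensionless).
#' @export
bulk_conductivity_ratio <- function(set, A, B) {
  A <- match.arg(A, c("l", "t", "n")); B <- match.arg(B, c("l", "t", "n"))
  num <- set[[paste0("g_i", A)]] + set[[paste0("g_e", A)]]
  den <- set[[paste0("g_i", B)]] + set[[paste0("g_e", B)]]
  if (den == 0) stop("degenerate parameters: zero denominator")
  num / den
}

#' Conduction velocity ratio between two tissue directions
#'
#' c_A/c_B = sqrt( ((g_iB + g_eB)/(g_iB g_eB)) * ((g_iA g_eA)/(g_iA + g_eA)) ),
#' i.e. the square root of the ratio of harmonic-mean conductivities.
#'
#' @inheritParams bulk_conductivity_ratio
#' @return The velocity ratio (dimensionless).
#' @export
velocity_ratio <- function(set, A, B) {
  A <- match.arg(A, c("l", "t", "n")); B <- match.arg(B, c("l", "t", "n"))
  giA <- set[[paste0("g_i", A)]]; geA <- set[[paste0("g_e", A)]]
  giB <- set[[paste0("g_i", B)]]; geB <- set[[paste0("g_e", B)]]
  if (any(c(giA, geA, giB, geB) == 0)) stop("degenerate parameters: zero conductivity")
  sqrt(((giB + geB) / (giB * geB)) * ((giA * geA) / (giA + geA)))
}

#' Load the literature table of measured/modelled conductivities
#' @return Data frame with columns study, type, animal and the six
#'   conductivities (NA where a study reports no value).
#' @export
literature_table <- function() {
  path <- system.file("extdata", "table1_conductivities.csv", package = "epduq")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Column-wise summary of the literature conductivity table
#'
#' Mean and standard deviation per conductivity over the non-missing
#' entries.  Both divisor conventions reproduce the customary printed
#' summary at one decimal place; the sample (n-1) convention is the default
#' and the convention used is recorded in the result.
#'
#' @param table literature table as from [literature_table()]
#' @param convention \code{"sample"} (divisor n-1) or \code{"population"}
#' @return List with \code{mean}, \code{sd} (named vectors), \code{n}
#'   (non-missing counts) and \code{convention}.
#' @export
literature_summary <- function(table = literature_table(),
                               convention = c("sample", "population")) {
  convention <- match.arg(convention)
  cols <- intersect(.CONDUCTIVITIES, names(table))
  mu <- s <- n <- setNames(numeric(length(cols)), cols)
  for (cl in cols) {
    v <- table[[cl]]; v <- v[!is.na(v)]
    if (length(v) == 0) stop("missing data: column ", cl, " is empty")
    mu[cl] <- mean(v); n[cl] <- length(v)
    s[cl] <- if (convention == "sample") {
      if (length(v) > 1) sd(v) else 0
    } else sqrt(mean((v - mean(v))^2))
  }
  list(mean = mu, sd = s, n = n, convention = convention)
}

#' Conductivity ratio features for ratio-based regression
#'
#' Computes, per design point, the seven conductivity ratios used for
#' ratio-versus-output regression: g_il/g_el, g_il/g_it, g_it/g_et,
#' g_il/g_in, g_in/g_en, g_el/g_et, g_el/g_en.
#'
#' @param design matrix or data frame of physical parameters with the six
#'   conductivity columns named g_il, g_el, g_it, g_et, g_in, g_en
#' @return Matrix with one column per ratio.
#' @export
ratio_features <- function(design) {
  design <- as.matrix(design[, .CONDUCTIVITIES, drop = FALSE])
  if (any(design <= 0)) stop("conductivities must be positive")
  out <- cbind(
    "g_il/g_el" = design[, "g_il"] / design[, "g_el"],
    "g_il/g_it" = design[, "g_il"] / design[, "g_it"],
    "g_it/g_et" = design[, "g_it"] / design[, "g_et"],
    "g_il/g_in" = design[, "g_il"] / design[, "g_in"],
    "g_in/g_en" = design[, "g_in"] / design[, "g_en"],
    "g_el/g_et" = design[, "g_el"] / design[, "g_et"],
    "g_el/g_en" = design[, "g_el"] / design[, "g_en"])
  out
}
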