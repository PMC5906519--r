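# Stochastic collocation: nested Clenshaw-Curtis rules combined by
# Smolyak's method, for the uniform probability measure on [0,1]^d.

#' One-dimensional Clenshaw-Curtis rule on [0,1]
#'
#' Nested growth m(0) = 1 (midpoint), m(l) = 2^l + 1.  Weights are for the
#' uniform probability measure (they sum to 1).
#'
#' @param level integer rule level >= 0
#' @return List with \code{x} (nodes in [0,1]) and \code{w} (weights).
#' @export
cc_rule <- function(level) {
  if (level < 0) stop("level must be >= 0")
  if (level == 0) return(list(x = 0.5, w = 1))
  m <- 2^level + 1
  N <- m - 1
  j <- 0:N
  x <- (1 - cospi(j / N)) / 2  # cospi is exact at dyadic arguments -> nested
  # classic Clenshaw-Curtis weights on [-1,1], then normalized to measure 1
  w <- numeric(m)
  kmax <- N %/% 2
  for (jj in j) {
    k <- seq_len(kmax)
    b <- ifelse(k == N / 2, 1, 2)
    w[jj + 1] <- (1 - sum(b / (4 * k^2 - 1) * cos(2 * k * jj * pi / N))) / N
  }
  w[c(1, m)] <- w[c(1, m)] / 2
  w <- w * 2          # weights on [-1,1] sum to 2 ...
  list(x = x, w = w / 2)  # ... renormalize to the probability measure
}

# all multi-indices i >= 0 with |i| = k, d parts
.compositions <- function(k, d) {
  if (d == 1) return(matrix(k, 1, 1))
  out <- NULL
  for (first in 0:k) {
    rest <- .compositions(k - first, d - 1)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

#' Smolyak sparse grid of Clenshaw-Curtis points
#'
#' Builds the level-\code{level} Smolyak sparse quadrature grid in
#' \code{d} dimensions from nested Clenshaw-Curtis rules (1-D growth
#' 1, 3, 5, 9, ...), for the uniform probability measure on [0,1]^d.
#' Weights may be negative but sum to 1; node sets are nested across levels.
#'
#' @param d dimension (>= 1)
#' @param level Smolyak level (>= 0)
#' @return A \code{sparse_grid}: list with \code{nodes} (m x d matrix),
#'   \code{weights}, \code{level}, \code{d}.
#' @export
smolyak_grid <- function(d, level) {
  stopifnot(d >= 1, level >= 0)
  rules <- lapply(0:level, cc_rule)
  acc <- new.env(parent = emptyenv())
  key_of <- function(pt) paste(sprintf("%.17g", pt), collapse = ",")
  lo <- max(0L, level - d + 1L)
  for (k in lo:level) {
    coef <- (-1)^(level - k) * choose(d - 1, level - k)
    if (coef == 0) next
    idx <- .compositions(k, d)
    for (r in seq_len(nrow(idx))) {
      iv <- idx[r, ]
      xs <- lapply(iv, function(l) rules[[l + 1]]$x)
      ws <- lapply(iv, function(l) rules[[l + 1]]$w)
      grid <- as.matrix(expand.grid(xs, KEEP.OUT.ATTRS = FALSE))
      wgrid <- Reduce(function(a, b) as.vector(outer(a, b)), ws)
      for (p in seq_len(nrow(grid))) {
        key <- key_of(grid[p, ])
        cur <- if (!is.null(acc[[key]])) acc[[key]] else list(pt = grid[p, ], w = 0)
        cur$w <- cur$w + coef * wgrid[p]
        acc[[key]] <- cur
      }
    }
  }
  keys <- ls(acc)
  nodes <- matrix(unlist(lapply(keys, function(k) acc[[k]]$pt)),
                  ncol = d, byrow = TRUE)
  weights <- vapply(keys, function(k) acc[[k]]$w, numeric(1))
  ord <- do.call(order, lapply(seq_len(d), function(j) nodes[, j]))
  structure(list(nodes = unname(nodes[ord, , drop = FALSE]),
                 weights = unname(weights[ord]),
                 level = level, d = d),
            class = "sparse_grid")
}

#' @export
print.sparse_grid <- function(x, ...) {
  cat("sparse_grid: level", x$level, "in", x$d, "dimensions,",
      nrow(x$nodes), "nodes (sum of weights ",
      format(sum(x$weights)), ")\n")
  invisible(x)
}

#' Weighted mean and standard-deviation fields by stochastic collocation
#'
#' Evaluates a simulator at every sparse-grid node (mapped to the physical
#' box by the given ranges over the named \code{vary} inputs, other inputs
#' held at \code{fixed}) and returns the weighted mean field
#' \eqn{\bar\phi = \sum_j w_j \phi^{(j)}} and standard-deviation field
#' \eqn{(\sum_j w_j (\phi^{(j)} - \bar\phi)^2)^{1/2}}.  Negative variance
#' accumulations (possible with negative Smolyak weights) are clipped to 0
#' before the square root.
#'
#' @param simulator function taking a named vector of physical parameters
#'   and returning an [epd] (or plain numeric field)
#' @param grid a \code{sparse_grid} whose dimension equals
#'   \code{length(vary)}
#' @param ranges a \code{parameter_ranges}
#' @param vary names of the varied inputs, in grid column order
#' @param fixed named vector of the remaining physical parameters (may
#'   include e.g. the ischaemic depth for simulators that accept it)
#' @return List with \code{mean} and \code{std} (same shape as the simulator
#'   output; \code{epd} objects when the simulator returns them),
#'   \code{evaluations} (number of simulator calls).
#' @export
pc_field_stats <- function(simulator, grid, ranges = default_ranges(),
                           vary = .CONDUCTIVITIES, fixed = NULL) {
  stopifnot(grid$d == length(vary))
  m <- nrow(grid$nodes)
  fields <- vector("list", m)
  template <- NULL
  for (j in seq_len(m)) {
    u <- setNames(grid$nodes[j, ], vary)
    phys <- denormalize(u, ranges)
    pars <- c(phys, fixed[setdiff(names(fixed), vary)])
    out <- tryCatch(simulator(pars), error = function(e)
      stop("simulator failed at node ", j, ": ", conditionMessage(e)))
    if (inherits(out, "epd")) {
      if (is.null(template)) template <- out
      fields[[j]] <- out$values
    } else fields[[j]] <- out
  }
  w <- grid$weights
  mean_f <- Reduce(`+`, Map(function(f, wj) wj * f, fields, w))
  var_f <- Reduce(`+`, Map(function(f, wj) wj * (f - mean_f)^2, fields, w))
  std_f <- sqrt(pmax(var_f, 0))
  wrap <- function(v) {
    if (is.null(template)) return(v)
    e <- template; e$values <- v; e
  }
  list(mean = wrap(mean_f), std = wrap(std_f), evaluations = m)
}

#' Correlation and relative error between two fields
#'
#' Pearson correlation over nodes and the relative error
#' \eqn{\|a-b\|_2 / \|a\|_2} (ratio of Euclidean norms, with \code{a} the
#' reference).
#'
#' @param a,b \code{epd} objects or numeric arrays on identical grids
#' @return List with \code{correlation} and \code{relative_error}.
#' @export
compare_fields <- function(a, b) {
  va <- if (inherits(a, "epd")) a$values else a
  vb <- if (inherits(b, "epd")) b$values else b
  if (!identical(dim(va), dim(vb))) stop("fields must share a grid")
  na <- sqrt(sum(va^2))
  if (na == 0) stop("undefined metric: zero-norm reference field")
  list(correlation = cor(as.vector(va), as.vector(vb)),
       relative_error = sqrt(sum((va - vb)^2)) / na)
}
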