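# Partial least squares regression by NIPALS: components that maximize
# input-output covariance, yielding signed regression coefficients on
# standardized scales.

#' Fit a PLS regression by the NIPALS algorithm
#'
#' Columns of X and Y are standardized internally to zero mean and unit
#' variance; components are extracted by the classical NIPALS iteration
#' with X-deflation, and regression coefficients are returned on the
#' standardized scales.  Coefficient magnitudes are meaningful only relative
#' to other coefficients of the same output.
#'
#' @param X n x p input matrix
#' @param Y n x q output matrix (or vector)
#' @param n_components number of latent components (default min(p, 8))
#' @param tol convergence tolerance of the inner NIPALS iteration
#' @return A \code{pls_model}: list with standardized \code{coefficients}
#'   (p x q), \code{scores}, \code{loadings}, \code{weights},
#'   \code{n_components}, and the standardization constants.
#' @export
fit_nipals <- function(X, Y, n_components = NULL, tol = 1e-10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (n <= p) stop("need more observations than inputs")
  if (is.null(n_components)) n_components <- min(p, 8)
  a <- min(n_components, p)
  mx <- colMeans(X); sx <- apply(X, 2, sd)
  my <- colMeans(Y); sy <- apply(Y, 2, sd)
  if (any(sx == 0))
    stop("degenerate input: zero-variance column ",
         paste(colnames(X)[sx == 0], collapse = ", "))
  if (any(sy == 0))
    stop("degenerate output: zero-variance column ",
         paste(colnames(Y)[sy == 0], collapse = ", "))
  Xs <- scale(X, mx, sx); Ys <- scale(Y, my, sy)
  E <- Xs; F <- Ys
  W <- P <- matrix(0, p, a)
  C <- matrix(0, q, a)
  Tm <- matrix(0, n, a)
  for (k in seq_len(a)) {
    u <- F[, which.max(apply(F, 2, var))]
    t_old <- rep(Inf, n)
    for (it in 1:500) {
      w <- crossprod(E, u); w <- w / sqrt(sum(w^2))
      tt <- E %*% w
      cc <- crossprod(F, tt) / sum(tt^2)
      if (sqrt(sum(cc^2)) == 0) break
      u <- F %*% cc / sum(cc^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    pp <- crossprod(E, tt) / sum(tt^2)
    E <- E - tt %*% t(pp)
    F <- F - tt %*% t(cc)
    W[, k] <- w; P[, k] <- pp; C[, k] <- cc; Tm[, k] <- tt
  }
  B <- W %*% solve(crossprod(P, W), t(C))
  rownames(B) <- colnames(X); colnames(B) <- colnames(Y)
  structure(list(coefficients = B, scores = Tm, loadings = P, weights = W,
                 y_loadings = C, n_components = a,
                 x_center = mx, x_scale = sx, y_center = my, y_scale = sy),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("pls_model:", x$n_components, "components; standardized coefficients:\n")
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Predict from a PLS model (original scales)
#' @param object a \code{pls_model}
#' @param Xnew new input matrix
#' @param ... unused
#' @return Matrix of predictions on the original output scales.
#' @export
predict.pls_model <- function(object, Xnew, ...) {
  Xs <- scale(as.matrix(Xnew), object$x_center, object$x_scale)
  Ys <- Xs %*% object$coefficients
  sweep(sweep(Ys, 2, object$y_scale, "*"), 2, object$y_center, "+")
}

#' Standardized PLS coefficients of outputs against inputs
#'
#' Convenience wrapper around [fit_nipals()] returning just the
#' standardized coefficient table (inputs x outputs).
#'
#' @inheritParams fit_nipals
#' @return p x q coefficient matrix.
#' @export
pls_coefficients <- function(X, Y, n_components = NULL) {
  fit_nipals(X, Y, n_components)$coefficients
}
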