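# Passive bidomain / blood volume-conductor solver.
#
# Vertex-centred assembly on trilinear hexahedra: the diagonal tensor terms
# use edge-midpoint (reduced) quadrature, which reduces exactly to the
# classic 7-point finite-volume flux stencil for diagonal tensors on uniform
# grids; the fibre-rotation xy cross-term uses exact quadrature of the
# trilinear gradients.  Both parts discretize the symmetric bilinear form
# integral(grad v . M grad u), so the assembled operator is symmetric and,
# because the reduced rule over-integrates the diagonal part, coercive.
#
# Governing system: div((Mi+Me) grad phi_e) = -div(Mi grad phi_m) in the
# tissue, laplace(phi_b) = 0 in the blood (conductivity g_b), phi and total
# normal current continuous at the endocardium (nodes shared), insulated on
# the sides and the epicardium (natural BC), phi_b = 0 at the bottom of the
# blood (Dirichlet).  The right-hand side applies the identical bilinear
# form with Mi to phi_m restricted to tissue cells, so the source flux is
# zeroed across insulated boundaries along with the diffusive flux.

.epduq_cache <- new.env(parent = emptyenv())

# 8x8 local templates; local node order n = 1..8 with corner offsets
# dx = bit0, dy = bit1, dz = bit2
.local_templates <- function() {
  bits <- cbind(dx = rep(0:1, 4), dy = rep(rep(0:1, each = 2), 2),
                dz = rep(0:1, each = 4))
  edge_tmpl <- function(dir) {
    other <- setdiff(1:3, dir)
    ka <- kb <- v <- NULL
    for (a in 1:8) for (b in 1:8) {
      if (bits[a, dir] == 0 && bits[b, dir] == 1 &&
          all(bits[a, other] == bits[b, other])) {
        ka <- c(ka, a, b, a, b); kb <- c(kb, a, b, b, a)
        v <- c(v, 1, 1, -1, -1)
      }
    }
    list(ka = ka, kb = kb, v = v)
  }
  # S_ab = int (dNa/dxi)(dNb/deta) over unit cube; cross = S + t(S)
  S <- matrix(0, 8, 8)
  for (a in 1:8) for (b in 1:8) {
    sxa <- if (bits[a, 1] == 1) 1 else -1
    syb <- if (bits[b, 2] == 1) 1 else -1
    Iz <- if (bits[a, 3] == bits[b, 3]) 1 / 3 else 1 / 6
    S[a, b] <- sxa * syb * 0.25 * Iz
  }
  Kxy <- S + t(S)
  nz <- which(abs(Kxy) > 1e-15, arr.ind = TRUE)
  list(Ex = edge_tmpl(1), Ey = edge_tmpl(2), Ez = edge_tmpl(3),
       Exy = list(ka = nz[, 1], kb = nz[, 2], v = Kxy[nz]),
       bits = bits)
}

# per-mesh precomputation: cell->node incidence and geometric factors
.mesh_structure <- function(mesh) {
  key <- paste("struct", mesh$nx, mesh$ny, mesh$nz, mesh$nz_tissue,
               sprintf("%.6f", mesh$x[2]), sep = "_")
  if (!is.null(.epduq_cache[[key]])) return(.epduq_cache[[key]])
  tm <- .local_templates()
  nxn <- mesh$nx + 1; nyn <- mesh$ny + 1; nzn <- mesh$nz + 1
  cells <- expand.grid(ix = seq_len(mesh$nx), iy = seq_len(mesh$ny),
                       iz = seq_len(mesh$nz))
  node_id <- function(ix, iy, iz) ix + nxn * (iy - 1) + nxn * nyn * (iz - 1)
  nodes <- matrix(0L, nrow(cells), 8)
  for (n in 1:8) {
    b <- tm$bits[n, ]
    nodes[, n] <- node_id(cells$ix + b[1], cells$iy + b[2], cells$iz + b[3])
  }
  hx <- diff(mesh$x)[cells$ix]; hy <- diff(mesh$y)[cells$iy]
  hz <- diff(mesh$z)[cells$iz]
  zc <- (mesh$z[cells$iz] + mesh$z[cells$iz + 1]) / 2
  tissue <- cells$iz <= mesh$nz_tissue
  idx <- function(t) list(II = as.vector(nodes[, t$ka]),
                          JJ = as.vector(nodes[, t$kb]), v = t$v)
  st <- list(nodes = nodes, hx = hx, hy = hy, hz = hz, zc = zc,
             tissue = tissue, n_nodes = nxn * nyn * nzn,
             nxn = nxn, nyn = nyn, nzn = nzn,
             gx = hy * hz / (4 * hx), gy = hx * hz / (4 * hy),
             gz = hx * hy / (4 * hz),
             tri = lapply(tm[c("Ex", "Ey", "Ez", "Exy")], idx))
  .epduq_cache[[key]] <- st
  st
}

# triplets of the bilinear form for given per-cell tensor entries
# (Mxx, Myy, Mzz, Mxy); cells outside `use` contribute nothing
.form_triplets <- function(st, Mxx, Myy, Mzz, Mxy, use = NULL) {
  cf <- list(Mxx * st$gx, Myy * st$gy, Mzz * st$gz, Mxy * st$hz)
  if (!is.null(use)) cf <- lapply(cf, function(v) ifelse(use, v, 0))
  II <- JJ <- XX <- vector("list", 4)
  for (k in 1:4) {
    t <- st$tri[[k]]
    II[[k]] <- t$II; JJ[[k]] <- t$JJ
    XX[[k]] <- as.vector(outer(cf[[k]], t$v))
  }
  list(i = unlist(II), j = unlist(JJ), x = unlist(XX))
}

# per-cell tensor entries of a rotated orthotropic tensor with principal
# values (gl, gt, gn) and fibre angle theta(z) = ROT * z (degrees)
.cell_tensor <- function(st, gl, gt, gn, ROT, g_b = NULL) {
  th <- ifelse(st$tissue, 2 * (ROT * pmin(st$zc, 1)) * pi / 180, 0)
  P <- (gl + gt) / 2; Q <- (gl - gt) / 2
  Mxx <- ifelse(st$tissue, P + Q * cos(th), g_b %||% 0)
  Myy <- ifelse(st$tissue, P - Q * cos(th), g_b %||% 0)
  Mzz <- ifelse(st$tissue, gn, g_b %||% 0)
  Mxy <- ifelse(st$tissue, Q * sin(th), 0)
  list(Mxx = Mxx, Myy = Myy, Mzz = Mzz, Mxy = Mxy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cached sparsity pattern of the reduced (bottom-eliminated) symmetric
# operator: upper-triangle triplet selector, CSC slot positions, skeleton
.assembly_pattern <- function(mesh, st) {
  key <- paste("pattern", mesh$nx, mesh$ny, mesh$nz, mesh$nz_tissue,
               sprintf("%.6f", mesh$x[2]), sep = "_")
  if (!is.null(.epduq_cache[[key]])) return(.epduq_cache[[key]])
  nk <- st$n_nodes - st$nxn * st$nyn
  ii <- unlist(lapply(st$tri, `[[`, "II"))
  jj <- unlist(lapply(st$tri, `[[`, "JJ"))
  sel <- ii <= jj & jj <= nk
  ckey <- (jj[sel] - 1) * nk + ii[sel]
  uk <- sort(unique(ckey))
  pos <- match(ckey, uk)
  A0 <- Matrix::sparseMatrix(i = ii[sel], j = jj[sel],
                             x = rep(1, sum(sel)), dims = c(nk, nk),
                             symmetric = TRUE)
  stopifnot(length(A0@x) == length(uk))
  pat <- list(sel = sel, pos = pos, A0 = A0, nk = nk)
  .epduq_cache[[key]] <- pat
  pat
}

#' Assemble the coupled bidomain/blood linear system
#'
#' Builds the symmetric stiffness operator of the coupled tissue+blood
#' problem (one unknown per node, endocardial interface nodes shared) and
#' the right-hand side -div(Mi grad phi_m) discretized with the same flux
#' stencil, restricted to tissue cells.  With \code{reduce = TRUE} (the
#' default) the Dirichlet condition phi_b = 0 on the bottom blood boundary
#' is eliminated and the reduced symmetric positive-definite operator is
#' returned; \code{reduce = FALSE} returns the full natural-boundary
#' operator over all nodes (useful for stencil and conservation checks).
#'
#' @param mesh a \code{mesh}
#' @param cond a \code{conductivity_set} (includes g_b)
#' @param ROT transmural fibre rotation [degrees]
#' @param phi_m transmembrane field on mesh nodes [mV], e.g. from
#'   [transmembrane_field()]
#' @param reduce eliminate the bottom Dirichlet nodes?
#' @return List with sparse symmetric \code{A}, \code{b}, \code{reduced},
#'   \code{bottom} (indices of the Dirichlet phi_b = 0 nodes) and the mesh
#'   structure.
#' @export
assemble_bidomain <- function(mesh, cond, ROT, phi_m, reduce = TRUE) {
  st <- .mesh_structure(mesh)
  stopifnot(length(phi_m) == st$n_nodes)
  Tie <- .cell_tensor(st, cond[["g_il"]] + cond[["g_el"]],
                      cond[["g_it"]] + cond[["g_et"]],
                      cond[["g_in"]] + cond[["g_en"]], ROT,
                      g_b = cond[["g_b"]])
  if (reduce) {
    pat <- .assembly_pattern(mesh, st)
    cf <- list(Tie$Mxx * st$gx, Tie$Myy * st$gy, Tie$Mzz * st$gz,
               Tie$Mxy * st$hz)
    xs <- unlist(lapply(seq_along(st$tri), function(k)
      as.vector(outer(cf[[k]], st$tri[[k]]$v))))[pat$sel]
    A <- pat$A0
    A@x <- as.vector(rowsum(xs, pat$pos, reorder = TRUE))
  } else {
    tr <- .form_triplets(st, Tie$Mxx, Tie$Myy, Tie$Mzz, Tie$Mxy)
    A <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                              dims = c(st$n_nodes, st$n_nodes))
  }
  Ti <- .cell_tensor(st, cond[["g_il"]], cond[["g_it"]], cond[["g_in"]], ROT)
  # only tissue cells touching the support of phi_m contribute to the load
  touched <- rowSums(abs(matrix(phi_m[st$nodes], ncol = 8)) > 0) > 0
  use <- st$tissue & touched
  tri <- .form_triplets(st, Ti$Mxx, Ti$Myy, Ti$Mzz, Ti$Mxy, use = use)
  nzt <- tri$x != 0
  bv <- -as.vector(rowsum(tri$x[nzt] * phi_m[tri$j[nzt]],
                          tri$i[nzt], reorder = TRUE))
  bi <- sort(unique(tri$i[nzt]))
  b <- numeric(st$n_nodes); b[bi] <- bv
  bottom <- seq.int(st$n_nodes - st$nxn * st$nyn + 1, st$n_nodes)
  if (reduce) b <- b[-bottom]
  list(A = A, b = b, reduced = reduce, bottom = bottom,
       structure = st, mesh = mesh)
}

#' Solve the assembled bidomain system
#'
#' Eliminates the bottom-blood Dirichlet nodes (phi_b = 0) and solves the
#' reduced symmetric positive-definite system by sparse Cholesky
#' factorization (\code{method = "direct"}, the default for desk-scale
#' meshes) or by Jacobi-preconditioned conjugate gradients
#' (\code{method = "cg"}, for large meshes).
#'
#' @param system list from [assemble_bidomain()]
#' @param method \code{"direct"} or \code{"cg"}
#' @param tol relative residual tolerance (must lie in (0,1))
#' @param maxit maximum CG iterations
#' @return A \code{potential_solution}: node potentials \code{phi} (tissue
#'   phi_e and blood phi_b in one vector, zero on the bottom boundary),
#'   \code{residual} (relative), \code{iterations}, \code{mesh}.
#' @export
solve_bidomain <- function(system, method = c("direct", "cg"),
                           tol = 1e-8, maxit = 10000L) {
  method <- match.arg(method)
  if (tol <= 0 || tol >= 1) stop("tolerance must lie in (0, 1)")
  keep <- setdiff(seq_len(system$structure$n_nodes), system$bottom)
  if (isTRUE(system$reduced)) {
    A <- system$A
    b <- system$b
  } else {
    A <- Matrix::forceSymmetric(system$A[keep, keep], uplo = "U")
    b <- system$b[keep]
  }
  nb <- sqrt(sum(b^2))
  if (nb == 0) {
    phi <- numeric(system$structure$n_nodes)
    return(structure(list(phi = phi, residual = 0, iterations = 0L,
                          mesh = system$mesh), class = "potential_solution"))
  }
  if (method == "direct") {
    ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE, super = TRUE)
    xr <- as.vector(Matrix::solve(ch, b))
    it <- 1L
  } else {
    d <- Matrix::diag(A)
    x <- numeric(length(b)); r <- b; z <- r / d; p <- z
    rz <- sum(r * z); it <- 0L
    while (sqrt(sum(r^2)) / nb > tol && it < maxit) {
      Ap <- as.vector(A %*% p)
      alpha <- rz / sum(p * Ap)
      x <- x + alpha * p; r <- r - alpha * Ap
      z <- r / d; rz_new <- sum(r * z)
      p <- z + (rz_new / rz) * p; rz <- rz_new; it <- it + 1L
    }
    if (sqrt(sum(r^2)) / nb > tol)
      stop("solver failed to converge: relative residual ",
           format(sqrt(sum(r^2)) / nb), " after ", it, " iterations")
    xr <- x
  }
  phi <- numeric(system$structure$n_nodes)
  phi[keep] <- xr
  res <- sqrt(sum((b - as.vector(A %*% xr))^2)) / nb
  structure(list(phi = phi, residual = res, iterations = it,
                 mesh = system$mesh), class = "potential_solution")
}

#' @export
print.potential_solution <- function(x, ...) {
  cat(sprintf("potential_solution on %d nodes (rel. residual %.2e)\n",
              length(x$phi), x$residual))
  invisible(x)
}

#' Extract the epicardial potential distribution from a solution
#'
#' @param solution a \code{potential_solution}
#' @return An [epd] on the z = 0 node slice.
#' @export
extract_epd <- function(solution) {
  m <- solution$mesh
  nxn <- m$nx + 1; nyn <- m$ny + 1
  vals <- matrix(solution$phi[seq_len(nxn * nyn)], nxn, nyn)
  epd(m$x, m$y, vals)
}

#' Simulate one epicardial potential distribution
#'
#' End-to-end single run: build the transmembrane source for the given
#' ischaemic depth, assemble the coupled bidomain/blood system for the given
#' conductivities and fibre rotation, solve, and slice the epicardium.
#' Results are memoized per (mesh, parameters, depth) within a session.
#'
#' @param pars named vector of physical inputs: \code{ROT} [degrees],
#'   \code{g_b} and the six bidomain conductivities [mS/cm]
#' @param depth ischaemic depth as a fraction of wall thickness
#' @param mesh a \code{mesh} (or preset name)
#' @param dphi_p plateau potential difference [mV]
#' @param cache memoize the run within the session?
#' @return An [epd].
#' @export
simulate_epd <- function(pars, depth, mesh = build_mesh("coarse"),
                         dphi_p = -30, cache = TRUE) {
  if (is.character(mesh)) mesh <- build_mesh(mesh)
  key <- paste("run", mesh$preset, mesh$nx, mesh$nz,
               paste(sprintf("%.12g", c(pars[.INPUTS], depth, dphi_p)),
                     collapse = "_"), sep = "|")
  if (cache && !is.null(.epduq_cache[[key]])) return(.epduq_cache[[key]])
  cdir <- getOption("epduq.cache.dir", NULL)
  cfile <- NULL
  if (!is.null(cdir)) {
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    cfile <- file.path(cdir, paste0(gsub("[^0-9a-zA-Z._-]", "_", key), ".rds"))
  }
  if (cache && !is.null(cfile) && file.exists(cfile)) {
    out <- readRDS(cfile)
    .epduq_cache[[key]] <- out
    return(out)
  }
  cond <- conductivity_set(pars[["g_il"]], pars[["g_el"]], pars[["g_it"]],
                           pars[["g_et"]], pars[["g_in"]], pars[["g_en"]],
                           g_b = pars[["g_b"]])
  phi_m <- transmembrane_field(mesh, depth, dphi_p = dphi_p)
  sys <- assemble_bidomain(mesh, cond, pars[["ROT"]], phi_m)
  sol <- solve_bidomain(sys)
  out <- extract_epd(sol)
  if (cache) {
    .epduq_cache[[key]] <- out
    if (!is.null(cfile)) saveRDS(out, cfile)
  }
  out
}

#' Clear the in-session solver cache
#' @return Invisibly, the number of entries removed.
#' @export
clear_run_cache <- function() {
  keys <- ls(.epduq_cache)
  runs <- keys[startsWith(keys, "run|")]
  rm(list = runs, envir = .epduq_cache)
  invisible(length(runs))
}
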