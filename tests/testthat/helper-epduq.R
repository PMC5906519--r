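# shared fixtures: tiny uniform meshes and canonical parameter sets

mean_pars <- function() default_ranges()$mean

# uniform all-tissue cube mesh on [0,1]^3 for operator/stencil checks
unit_cube_mesh <- function(n) {
  g <- seq(0, 1, length.out = n + 1)
  structure(list(x = g, y = g, z = g, nx = n, ny = n, nz = n,
                 nz_tissue = n, n_nodes = (n + 1)^3, n_cells = n^3,
                 preset = "unitcube"),
            class = "mesh")
}

# assemble the full (natural-BC) operator for a spatially constant tensor
constant_tensor_operator <- function(mesh, Mxx, Myy, Mzz, Mxy = 0) {
  st <- epduq:::.mesh_structure(mesh)
  nc <- length(st$hx)
  tr <- epduq:::.form_triplets(st, rep(Mxx, nc), rep(Myy, nc),
                               rep(Mzz, nc), rep(Mxy, nc))
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                       dims = c(st$n_nodes, st$n_nodes))
}

# node coordinate arrays of a mesh, x fastest
mesh_nodes <- function(mesh) {
  expand.grid(x = mesh$x, y = mesh$y, z = mesh$z)
}
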