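# Trilinear hexahedral FEM for the quasi-static current-flow problem
# div(sigma grad phi) = 0 with Neumann (injected current) boundary data.
# Unit chain, locked by tests: sigma [S/cm], grid spacing [mm -> cm],
# injected currents [mA] => potentials [mV], current density [uA/cm^2].

# reference stiffness of the trilinear element on the unit cube, unit
# conductivity: K_ij = int grad(N_i) . grad(N_j) dV via 2x2x2 Gauss
# quadrature (exact: the integrand is at most quadratic per coordinate).
# Corner order: index = 1 + di + 2*dj + 4*dk, (di,dj,dk) in {0,1}^3.
element_stiffness_ref <- function(n_gauss = 2L) {
  gp <- switch(as.character(n_gauss),
    "2" = list(x = 0.5 + c(-1, 1) / (2 * sqrt(3)), w = c(0.5, 0.5)),
    "4" = {
      a <- sqrt(3 / 7 - 2 / 7 * sqrt(6 / 5))
      b <- sqrt(3 / 7 + 2 / 7 * sqrt(6 / 5))
      wa <- (18 + sqrt(30)) / 36; wb <- (18 - sqrt(30)) / 36
      list(x = 0.5 + c(-b, -a, a, b) / 2, w = c(wb, wa, wa, wb) / 2)
    },
    stop("n_gauss must be 2 or 4"))
  corners <- as.matrix(expand.grid(di = 0:1, dj = 0:1, dk = 0:1))
  K <- matrix(0, 8, 8)
  for (ix in seq_along(gp$x)) for (iy in seq_along(gp$x))
    for (iz in seq_along(gp$x)) {
      xi <- gp$x[ix]; eta <- gp$x[iy]; zeta <- gp$x[iz]
      wq <- gp$w[ix] * gp$w[iy] * gp$w[iz]
      f <- function(d, t) ifelse(d == 1, t, 1 - t)
      df <- function(d) ifelse(d == 1, 1, -1)
      G <- cbind(df(corners[, 1]) * f(corners[, 2], eta) *
                   f(corners[, 3], zeta),
                 f(corners[, 1], xi) * df(corners[, 2]) *
                   f(corners[, 3], zeta),
                 f(corners[, 1], xi) * f(corners[, 2], eta) *
                   df(corners[, 3]))
      K <- K + wq * (G %*% t(G))
    }
  K
}

.fem_cache <- new.env(parent = emptyenv())

ref_stiffness <- function() {
  if (is.null(.fem_cache$K)) .fem_cache$K <- element_stiffness_ref(2L)
  .fem_cache$K
}

# voxel linear index (1-based, array order) -> (i,j,k)
vox_ijk <- function(v, dims) {
  v0 <- v - 1L
  i <- v0 %% dims[1]
  j <- (v0 %/% dims[1]) %% dims[2]
  k <- v0 %/% (dims[1] * dims[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

#' Check that the conduction domain is 6-connected
#' @keywords internal
check_connected <- function(mask) {
  visited <- array(FALSE, dim(mask))
  seed <- which(mask)[1]
  visited[seed] <- TRUE
  repeat {
    frontier <- array(FALSE, dim(mask))
    for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1)))
      frontier <- frontier | shift_array(visited, d)
    frontier <- frontier & mask & !visited
    if (!any(frontier)) break
    visited <- visited | frontier
  }
  n_left <- sum(mask & !visited)
  if (n_left > 0L)
    stop("conduction domain is disconnected: ", n_left,
         " voxels unreachable from the main component")
  invisible(TRUE)
}

#' Assemble the FEM system from a conductivity volume
#'
#' Builds the sparse symmetric stiffness matrix of the trilinear hexahedral
#' discretization on the conduction domain (non-air voxels). The assembled
#' operator is the pure-Neumann one: symmetric positive semi-definite with
#' the constant vector as null space.
#'
#' @param sigma a [conductivity_from_resistivity()] result (or any list
#'   with `sigma` array in S/cm and logical `mask`).
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param check connectivity check of the conduction domain (on by
#'   default; disable for speed on trusted phantoms).
#' @return object of class `fem_system`: `K` (dgCMatrix), `node_map`
#'   (array over the node grid: compact index or 0), `node_ids`
#'   (node-grid linear ids per compact index), `dims`, `h_cm`, `n_nodes`.
#' @export
assemble_fem <- function(sigma, voxel_size_mm = 1.0, check = TRUE) {
  mask <- sigma$mask
  sig <- sigma$sigma
  dims <- dim(mask)
  if (!any(mask)) stop("empty conduction domain")
  if (any(sig[mask] <= 0)) stop("sigma must be positive on the domain")
  if (check) check_connected(mask)
  h_cm <- voxel_size_mm / 10

  elems <- which(mask)
  ijk <- vox_ijk(elems, dims)
  nd <- dims + 1L
  corners <- as.matrix(expand.grid(di = 0:1, dj = 0:1, dk = 0:1))
  # node-grid linear ids of the 8 corners of every element
  corner_ids <- matrix(0L, length(elems), 8L)
  for (c8 in 1:8)
    corner_ids[, c8] <- node_id(ijk[, 1] + corners[c8, 1],
                                ijk[, 2] + corners[c8, 2],
                                ijk[, 3] + corners[c8, 3], dims)
  node_ids <- sort(unique(as.integer(corner_ids)))
  node_map <- integer(prod(nd))
  node_map[node_ids] <- seq_along(node_ids)
  n_nodes <- length(node_ids)
  compact <- matrix(node_map[corner_ids], ncol = 8L)

  Kref <- ref_stiffness()
  coef <- sig[elems] * h_cm
  ne <- length(elems)
  ii <- integer(64L * ne); jj <- integer(64L * ne); xx <- numeric(64L * ne)
  pos <- 0L
  for (a in 1:8) for (b in 1:8) {
    idx <- pos + seq_len(ne)
    ii[idx] <- compact[, a]
    jj[idx] <- compact[, b]
    xx[idx] <- coef * Kref[a, b]
    pos <- pos + ne
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(n_nodes, n_nodes))
  structure(list(K = K, node_map = node_map, node_ids = node_ids,
                 dims = dims, h_cm = h_cm, n_nodes = n_nodes,
                 elems = elems, corner_compact = compact,
                 sigma = sig),
            class = "fem_system")
}

#' Build the nodal load vector for a montage
#'
#' Each electrode's current (mA) is split uniformly over its footprint
#' nodes. The result sums to zero within 1e-12 mA for any zero-net-current
#' montage.
#'
#' @param system a [assemble_fem()] result.
#' @param montage a [build_montage()] result.
#' @return numeric load vector (mA) over compact node indices.
#' @export
build_load <- function(system, montage) {
  f <- numeric(system$n_nodes)
  for (e in montage$electrodes) {
    cn <- system$node_map[e$footprint$nodes]
    if (any(cn == 0L))
      stop("electrode ", e$site$label,
           " has footprint nodes outside the conduction domain")
    f[cn] <- f[cn] + e$current_mA / length(cn)
  }
  if (abs(sum(f)) > 1e-12)
    stop("load vector does not balance: net ", sum(f), " mA")
  f
}

#' Solve for the electric potential
#'
#' Jacobi-preconditioned conjugate gradients on the pure-Neumann system;
#' the constant mode is deflated each iteration and the solution reported
#' in the zero-mean gauge.
#'
#' @param system a [assemble_fem()] result.
#' @param f load vector from [build_load()] (mA).
#' @param tol relative residual tolerance (default 1e-8).
#' @param max_iter iteration cap.
#' @return object of class `potential_field`: `phi` (mV, compact node
#'   order), `iterations`, `relres`.
#' @export
solve_potential <- function(system, f, tol = 1e-8, max_iter = 20000L) {
  stopifnot(inherits(system, "fem_system"))
  if (abs(sum(f)) > 1e-9 * max(sum(abs(f)), 1))
    stop("load is not balanced (sum = ", sum(f), " mA)")
  K <- system$K
  res <- pcg_csc(K@p, K@i, K@x, f, tol, as.integer(max_iter), TRUE)
  if (!res$converged)
    stop("CG did not converge in ", max_iter,
         " iterations (relative residual ", signif(res$relres, 3), ")")
  structure(list(phi = res$x, iterations = res$iterations,
                 relres = res$relres), class = "potential_field")
}

#' Current density from the potential solution
#'
#' Evaluates `J = -sigma grad(phi)` at each voxel (element) centre using
#' the trilinear shape-function gradients, and converts to uA/cm^2.
#'
#' @param phi a [solve_potential()] result.
#' @param system the matching `fem_system`.
#' @return object of class `current_density_field`: arrays `Jx`, `Jy`,
#'   `Jz`, `Jmag` (uA/cm^2, 0 on air voxels).
#' @export
compute_current_density <- function(phi, system) {
  p <- phi$phi
  cc <- system$corner_compact
  h <- system$h_cm
  # corner index = 1 + di + 2 dj + 4 dk
  hi <- function(cols) p[cc[, cols[1]]] + p[cc[, cols[2]]] +
    p[cc[, cols[3]]] + p[cc[, cols[4]]]
  gx <- (hi(c(2, 4, 6, 8)) - hi(c(1, 3, 5, 7))) / (4 * h)  # mV/cm
  gy <- (hi(c(3, 4, 7, 8)) - hi(c(1, 2, 5, 6))) / (4 * h)
  gz <- (hi(c(5, 6, 7, 8)) - hi(c(1, 2, 3, 4))) / (4 * h)
  sig <- system$sigma[system$elems]
  dims <- system$dims
  Jx <- Jy <- Jz <- Jmag <- array(0, dims)
  # 1000: S/cm * mV/cm = mA/cm^2 -> uA/cm^2
  Jx[system$elems] <- -1000 * sig * gx
  Jy[system$elems] <- -1000 * sig * gy
  Jz[system$elems] <- -1000 * sig * gz
  Jmag[system$elems] <- sqrt(Jx[system$elems]^2 + Jy[system$elems]^2 +
                               Jz[system$elems]^2)
  structure(list(Jx = Jx, Jy = Jy, Jz = Jz, Jmag = Jmag),
            class = "current_density_field")
}

#' Net current crossing a transverse (z) plane
#'
#' Integrates `Jz` over the voxel layer `k` (flux in mA); used by the
#' conservation checks.
#' @param J a `current_density_field`.
#' @param k voxel layer index.
#' @param h_cm voxel size in cm.
#' @return flux in mA.
#' @export
plane_flux_mA <- function(J, k, h_cm) {
  sum(J$Jz[, , k]) * h_cm^2 / 1000
}
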