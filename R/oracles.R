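# Analytic oracles for solver validation: uniform slab closed form and the
# Legendre-series potential of point electrodes on a homogeneous sphere.

#' Uniform-slab validation problem
#'
#' A homogeneous cube with a uniform current applied across its top and
#' bottom faces has a potential linear in depth and a uniform current
#' density `I / A`. The load uses consistent (area-weighted) nodal values
#' so the exact solution lies in the FE space; the discrete solution then
#' matches to solver tolerance.
#'
#' @param n voxels per edge.
#' @param sigma_S_cm conductivity (S/cm).
#' @param I_mA injected current (mA).
#' @param voxel_size_mm voxel size (mm).
#' @param tol CG tolerance.
#' @return list: `J_expected` (uA/cm^2), `J_max_abs_err`, `phi_linearity`
#'   (max deviation of nodal phi from the best linear profile, mV),
#'   `flux_err_rel` (worst relative error of plane flux vs `I_mA`),
#'   `system`, `J`.
#' @export
slab_validation <- function(n = 20L, sigma_S_cm = 1.0, I_mA = 1.0,
                            voxel_size_mm = 1.0, tol = 1e-10) {
  dims <- c(n, n, n)
  sig <- list(sigma = array(sigma_S_cm, dims),
              mask = array(TRUE, dims))
  sys <- assemble_fem(sig, voxel_size_mm, check = FALSE)
  f <- numeric(sys$n_nodes)
  # consistent load for uniform current density on the z faces: each face
  # contributes I/(n^2) split as 1/4 per corner node
  per_face <- I_mA / n^2 / 4
  for (i in seq_len(n)) for (j in seq_len(n)) {
    for (o1 in 0:1) for (o2 in 0:1) {
      top <- sys$node_map[node_id(i + o1, j + o2, n + 1L, dims)]
      bot <- sys$node_map[node_id(i + o1, j + o2, 1L, dims)]
      f[top] <- f[top] + per_face
      f[bot] <- f[bot] - per_face
    }
  }
  phi <- solve_potential(sys, f, tol = tol)
  J <- compute_current_density(phi, sys)
  h_cm <- sys$h_cm
  area_cm2 <- (n * h_cm)^2
  J_expected <- I_mA / area_cm2 * 1000  # uA/cm^2
  J_err <- max(abs(J$Jmag - J_expected)) / J_expected
  # nodal phi linear in z: regress against node z-layer
  nid <- sys$node_ids
  kz <- (nid - 1L) %/% ((dims[1] + 1L) * (dims[2] + 1L))
  fitl <- stats::lm(phi$phi ~ kz)
  phi_lin <- max(abs(stats::residuals(fitl)))
  flux <- vapply(seq_len(n), function(k) plane_flux_mA(J, k, h_cm),
                 numeric(1))
  list(J_expected = J_expected, J_max_abs_err = J_err,
       phi_linearity = phi_lin,
       flux_err_rel = max(abs(abs(flux) - I_mA)) / I_mA,
       flux_mA = flux, system = sys, J = J, phi = phi)
}

#' Series potential for two point electrodes on a homogeneous sphere
#'
#' Interior potential of an insulated homogeneous sphere (radius `R_mm`,
#' conductivity `sigma_S_cm`) with current `I_mA` injected at surface
#' point `src` and withdrawn at `snk`:
#' `phi(r) = I/(4 pi sigma) * sum_{n>=1} (2n+1)/n * r^n / R^(n+1) *
#' [P_n(cos g_src) - P_n(cos g_snk)]` (mV with the package unit chain).
#'
#' @param points matrix of evaluation points (mm, rows), relative to the
#'   sphere centre.
#' @param src,snk unit vectors toward the source/sink surface points.
#' @param R_mm sphere radius (mm).
#' @param sigma_S_cm conductivity (S/cm).
#' @param I_mA injected current (mA).
#' @param n_terms series length.
#' @return potential (mV) at each point, zero-mean over the points.
#' @export
sphere_series_potential <- function(points, src, snk, R_mm, sigma_S_cm,
                                    I_mA = 1.0, n_terms = 120L) {
  src <- src / sqrt(sum(src^2)); snk <- snk / sqrt(sum(snk^2))
  r <- sqrt(rowSums(points^2))
  safe_r <- pmax(r, 1e-9)
  cg_src <- as.numeric(points %*% src) / safe_r
  cg_snk <- as.numeric(points %*% snk) / safe_r
  cg_src[r < 1e-9] <- 1; cg_snk[r < 1e-9] <- 1
  R_cm <- R_mm / 10
  r_cm <- r / 10
  rho <- r_cm / R_cm
  # Legendre recurrence P_n(x), accumulate the two expansions
  acc <- numeric(nrow(points))
  for (x in list(list(cg = cg_src, sgn = 1), list(cg = cg_snk, sgn = -1))) {
    Pm1 <- rep(1, length(acc))    # P_0
    P <- x$cg                     # P_1
    rn <- rho                     # rho^n at n = 1
    term_sum <- (2 * 1 + 1) / 1 * rn * P
    for (nn in 2:n_terms) {
      Pn <- ((2 * nn - 1) * x$cg * P - (nn - 1) * Pm1) / nn
      Pm1 <- P; P <- Pn
      rn <- rn * rho
      term_sum <- term_sum + (2 * nn + 1) / nn * rn * Pn
    }
    acc <- acc + x$sgn * term_sum
  }
  phi <- I_mA / (4 * pi * sigma_S_cm * R_cm) * acc
  phi - mean(phi)
}

#' Homogeneous-sphere validation of the FEM solver
#'
#' Voxelizes a homogeneous sphere, injects +/-I at the surface nodes
#' nearest two antipodal-ish electrode directions, solves, and compares
#' the FEM potential with the Legendre-series solution at interior voxel
#' centres (radii up to `frac_R` times R, excluding a 4 mm ball around each
#' electrode where the point-source series diverges).
#'
#' @param R_mm sphere radius (mm), default 25.
#' @param sigma_S_cm conductivity (S/cm).
#' @param voxel_size_mm grid resolution (mm), default 1.
#' @param frac_R evaluation region as a fraction of the radius.
#' @param tol CG tolerance.
#' @return list: `rms_rel_err`, `n_points`, `iterations`.
#' @export
sphere_validation <- function(R_mm = 25, sigma_S_cm = 0.01,
                              voxel_size_mm = 1.0, frac_R = 0.85,
                              tol = 1e-9) {
  h <- voxel_size_mm
  n <- ceiling(2 * R_mm / h) + 6L
  dims <- rep(as.integer(n), 3L)
  ctr <- dims * h / 2
  x <- (seq_len(dims[1]) - 0.5) * h - ctr[1]
  q <- outer(outer(x^2, x^2, "+"), x^2, "+")
  mask <- q <= R_mm^2
  sig <- list(sigma = array(sigma_S_cm * mask, dims), mask = mask)
  sys <- assemble_fem(sig, h, check = FALSE)

  e_src <- c(0, 0, 1)
  e_snk <- c(sin(2.5), 0, cos(2.5))  # ~143 degrees away
  nearest_surface_node <- function(u) {
    p <- ctr + u * R_mm
    nid <- sys$node_ids
    nd1 <- dims[1] + 1L
    i <- (nid - 1L) %% nd1
    j <- ((nid - 1L) %/% nd1) %% (dims[2] + 1L)
    k <- (nid - 1L) %/% (nd1 * (dims[2] + 1L))
    pos <- cbind(i, j, k) * h  # node (1,1,1) sits at 0 mm
    d2 <- (pos[, 1] - p[1])^2 + (pos[, 2] - p[2])^2 + (pos[, 3] - p[3])^2
    which.min(d2)
  }
  src_n <- nearest_surface_node(e_src)
  snk_n <- nearest_surface_node(e_snk)
  f <- numeric(sys$n_nodes)
  f[src_n] <- 1.0; f[snk_n] <- -1.0
  phi <- solve_potential(sys, f, tol = tol)

  vox <- which(mask)
  ijk <- vox_ijk(vox, dims)
  pts <- sweep(voxel_centers_mm(ijk, h), 2, ctr)
  r <- sqrt(rowSums(pts^2))
  d_src <- sqrt(rowSums(sweep(pts, 2, e_src * R_mm)^2))
  d_snk <- sqrt(rowSums(sweep(pts, 2, e_snk * R_mm)^2))
  keep <- r <= frac_R * R_mm & d_src > 4 & d_snk > 4
  pts <- pts[keep, , drop = FALSE]
  phi_ref <- sphere_series_potential(pts, e_src, e_snk, R_mm, sigma_S_cm)
  # FEM potential at voxel centres: average the 8 corner nodes
  cc <- sys$corner_compact[match(vox[keep], sys$elems), , drop = FALSE]
  phi_fem <- rowMeans(matrix(phi$phi[cc], nrow = nrow(cc)))
  phi_fem <- phi_fem - mean(phi_fem)
  phi_ref <- phi_ref - mean(phi_ref)
  rms <- sqrt(mean((phi_fem - phi_ref)^2)) / sqrt(mean(phi_ref^2))
  list(rms_rel_err = rms, n_points = nrow(pts),
       iterations = phi$iterations)
}
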