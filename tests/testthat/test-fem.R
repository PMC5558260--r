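test_that("reference element stiffness matches a higher-order quadrature", {
  K2 <- tesdose:::element_stiffness_ref(2L)
  K4 <- tesdose:::element_stiffness_ref(4L)   # independent quadrature rule
  expect_lt(max(abs(K2 - K4)), 1e-12)
  expect_lt(max(abs(K2 - t(K2))), 1e-14)      # symmetric
  expect_lt(max(abs(rowSums(K2))), 1e-14)     # constants in the null space
  expect_equal(diag(K2), rep(1 / 3, 8), tolerance = 1e-12)
})

test_that("assembly is linear in sigma and annihilates constants", {
  dims <- c(5L, 5L, 5L)
  mk <- function(s) list(sigma = array(s, dims), mask = array(TRUE, dims))
  s1 <- assemble_fem(mk(1.0), 1.0, check = FALSE)
  s2 <- assemble_fem(mk(2.0), 1.0, check = FALSE)
  expect_lt(max(abs(s1$K %*% rep(1, s1$n_nodes))), 1e-12)
  expect_lt(max(abs(2 * s1$K - s2$K)), 1e-12)
  expect_lt(max(abs(s1$K - Matrix::t(s1$K))), 1e-12)
})

test_that("disconnected conduction domains are reported", {
  dims <- c(7L, 3L, 3L)
  mask <- array(TRUE, dims)
  mask[4, , ] <- FALSE                        # split the bar in two
  sig <- list(sigma = array(1, dims) * mask, mask = mask)
  expect_error(assemble_fem(sig, 1.0, check = TRUE), "disconnected")
})

test_that("uniform slab reproduces the closed form exactly", {
  v <- slab_validation(n = 16L)
  expect_equal(v$J_expected, 1 / (1.6^2) * 1000)   # I/A in uA/cm^2
  expect_lt(v$J_max_abs_err, 1e-6)
  expect_lt(v$phi_linearity, 1e-8)
  expect_lt(v$flux_err_rel, 1e-3)
})

test_that("solutions are linear in the load and reciprocal", {
  dims <- c(10L, 10L, 10L)
  sig <- list(sigma = array(0.5, dims), mask = array(TRUE, dims))
  sys <- assemble_fem(sig, 1.0, check = FALSE)
  f <- numeric(sys$n_nodes)
  # two arbitrary, asymmetric injection nodes
  f[1] <- 1; f[sys$n_nodes %/% 3] <- -1
  p1 <- solve_potential(sys, f, tol = 1e-10)
  p2 <- solve_potential(sys, 2.5 * f, tol = 1e-10)
  expect_lt(max(abs(p2$phi - 2.5 * p1$phi)), 1e-6 * max(abs(p1$phi)))
  p3 <- solve_potential(sys, -f, tol = 1e-10)   # anode/cathode swap
  expect_lt(max(abs(p3$phi + p1$phi)), 1e-6 * max(abs(p1$phi)))
  # residual-based conservation: |K phi - f| small against ||f||
  r <- as.numeric(sys$K %*% p1$phi) - f
  expect_lt(sqrt(sum(r^2)) / sqrt(sum(f^2)), 1e-9)
})

test_that("unbalanced loads and non-convergence are errors", {
  dims <- c(4L, 4L, 4L)
  sig <- list(sigma = array(1, dims), mask = array(TRUE, dims))
  sys <- assemble_fem(sig, 1.0, check = FALSE)
  f <- numeric(sys$n_nodes); f[1] <- 1          # net current != 0
  expect_error(solve_potential(sys, f), "balanced")
  f[2] <- -1
  expect_error(solve_potential(sys, f, max_iter = 1L), "converge")
})

test_that("current density carries the uA/cm^2 unit chain", {
  # constant potential -> zero current
  dims <- c(6L, 6L, 6L)
  sig <- list(sigma = array(1, dims), mask = array(TRUE, dims))
  sys <- assemble_fem(sig, 1.0, check = FALSE)
  phi0 <- structure(list(phi = rep(3.7, sys$n_nodes)),
                    class = "potential_field")
  J0 <- compute_current_density(phi0, sys)
  expect_equal(max(J0$Jmag), 0)
  # imposed linear potential: phi = -z_cm (mV) on a sigma = 0.2 S/cm block
  # gives J = sigma * 1 mV/cm * 1000 = 200 uA/cm^2, straight +z
  sig2 <- list(sigma = array(0.2, dims), mask = array(TRUE, dims))
  sys2 <- assemble_fem(sig2, 1.0, check = FALSE)
  nid <- sys2$node_ids
  kz <- (nid - 1L) %/% ((dims[1] + 1L) * (dims[2] + 1L))  # node layer
  phi_lin <- structure(list(phi = -(kz * 0.1)), class = "potential_field")
  J <- compute_current_density(phi_lin, sys2)
  expect_equal(max(abs(J$Jz - 200)), 0, tolerance = 1e-9)
  expect_equal(max(abs(J$Jx)), 0, tolerance = 1e-12)
  expect_equal(unname(J$Jmag[3, 3, 3]), 200, tolerance = 1e-9)
})
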