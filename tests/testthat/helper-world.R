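# Shared fixtures, built in code and cached per test run. The "tiny world"
# is a 48^3 single-subject phantom with its FEM system; expensive pieces
# are computed lazily on first use.

.world <- new.env(parent = emptyenv())

tiny_spec <- function(seed = 3L) {
  cohort_spec(n_subjects = 2L, sex = c("female", "male"),
              grid_shape = c(48L, 48L, 48L), seed = seed)
}

tiny_world <- function() {
  if (is.null(.world$w)) {
    spec <- tiny_spec()
    ph <- build_phantom(sample_morphology(spec, 1L), spec,
                        sex = "female", subject_id = "S01")
    sigma <- phantom_conductivity(ph)
    sys <- assemble_fem(sigma, spec$voxel_size_mm, check = FALSE)
    sites <- place_1020_sites(ph)
    .world$w <- list(spec = spec, phantom = ph, sigma = sigma,
                     sys = sys, sites = sites)
  }
  .world$w
}

# a flat scalp slab masquerading as a head_phantom: scalp layer on top of
# a deep tissue block, air above; used for footprint-count oracles
flat_patch_phantom <- function(n = 31L, scalp_top = 10L) {
  lab <- array(tesdose:::TISSUE_CODES[["brain"]], c(n, n, scalp_top + 6L))
  lab[, , seq(scalp_top - 2L, scalp_top)] <-
    tesdose:::TISSUE_CODES[["scalp"]]
  lab[, , seq(scalp_top + 1L, scalp_top + 6L)] <-
    tesdose:::TISSUE_CODES[["air"]]
  w <- array(0.7, dim(lab))
  w[lab == tesdose:::TISSUE_CODES[["air"]]] <- 0
  structure(list(label = lab, water = w,
                 morphology = list(radii_scalp = c(n, n, scalp_top)),
                 sex = "female", subject_id = "FLAT", voxel_size_mm = 1.0,
                 center = c(n / 2, n / 2, 0)),
            class = "head_phantom")
}

# desk-scale acceptance run: 10 subjects (5 F / 5 M) on a 64^3 grid, one
# solve per configuration x site at 1 mA, fixed seed; cached across tests
acceptance_run <- function() {
  if (is.null(.world$acc)) {
    cfg <- default_config(n_subjects = 10L, n_female = 5L, grid = 64L,
                          seed = 42L, solver_tol = 1e-6)
    .world$acc <- suppressMessages(run_full_study(cfg, verbose = FALSE))
  }
  .world$acc
}

flat_patch_site <- function(n = 31L, scalp_top = 10L) {
  mid <- as.integer((n + 1L) / 2L)
  structure(list(label = "C3", voxel = c(mid, mid, scalp_top),
                 pos_mm = (c(mid, mid, scalp_top) - 0.5),
                 normal = c(0, 0, 1)),
            class = "electrode_site")
}
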