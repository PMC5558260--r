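# End-to-end orchestration: cohort -> conductivity -> montage -> solve ->
# dose -> mixed-effects ANOVA, with a JSON config, seeds and a manifest.

#' Default run configuration
#'
#' Nested list consumed by [run_full_study()]; serializable to/from JSON
#' with [write_config()] / [read_config()].
#'
#' @param n_subjects,n_female cohort composition (males fill the rest).
#' @param grid voxels per axis (cubic grid).
#' @param seed master seed.
#' @param out_dir output directory (`NULL` = no files written).
#' @param solver_tol,solver_max_iter CG settings.
#' @param noise_sd MRI simulation noise.
#' @param use_mri_channels when `TRUE` the conductivity is derived through
#'   the simulated T1/T2/PD channels and [combine_mri()]; when `FALSE`
#'   (default) directly from the ground-truth water fraction (identical at
#'   `noise_sd = 0` by the round-trip property).
#' @param independent_solves solve every intensity separately instead of
#'   scaling the 1 mA solution (verification mode).
#' @param write_volumes write NIfTI volumes per subject.
#' @return a list of class `run_config`.
#' @export
default_config <- function(n_subjects = 23L, n_female = 11L,
                           grid = 96L, seed = 1L, out_dir = NULL,
                           solver_tol = 1e-8, solver_max_iter = 20000L,
                           noise_sd = 0.0, use_mri_channels = TRUE,
                           independent_solves = FALSE,
                           write_volumes = FALSE) {
  structure(list(
    cohort = list(n_subjects = n_subjects, n_female = n_female,
                  grid = grid, seed = seed, noise_sd = noise_sd),
    resistivity = list(K = 16000, E = 4, D = 65,
                       weights = c(pd = 0.5, t2 = 0.25, t1 = 0.25),
                       use_mri_channels = use_mri_channels),
    montage = list(radius_mm = 5, ring_mm = 30,
                   intensities = c(0.5, 1.0, 2.0)),
    solver = list(tol = solver_tol, max_iter = solver_max_iter,
                  independent_solves = independent_solves),
    target = list(diameter_mm = 10),
    output = list(out_dir = out_dir, write_volumes = write_volumes)),
    class = "run_config")
}

#' @rdname default_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(cfg, class = "run_config")
}

config_cohort_spec <- function(config) {
  co <- config$cohort
  n_m <- co$n_subjects - co$n_female
  cohort_spec(n_subjects = co$n_subjects,
              sex = c(rep("female", co$n_female), rep("male", n_m)),
              grid_shape = rep(as.integer(co$grid), 3L),
              seed = co$seed)
}

#' Forward-model one subject: 6 solves, 18 dose rows
#'
#' Assembles the FEM system once per subject, solves each configuration x
#' site at 1 mA, and obtains the other intensities by exact linear scaling
#' (or by independent solves in verification mode).
#'
#' @param phantom,triplet one cohort entry.
#' @param config a `run_config`.
#' @return data frame of 18 dose rows.
#' @export
forward_subject <- function(phantom, triplet, config = default_config()) {
  rp <- resistivity_params(config$resistivity$K, config$resistivity$E,
                           config$resistivity$D)
  if (isTRUE(config$resistivity$use_mri_channels)) {
    v <- combine_mri(triplet, unlist(config$resistivity$weights))
    R <- resistivity_from_intensity(v, rp)
    sigma <- conductivity_from_resistivity(R, phantom$label)
  } else {
    sigma <- phantom_conductivity(phantom, rp)
  }
  sys <- assemble_fem(sigma, phantom$voxel_size_mm, check = FALSE)
  sites <- place_1020_sites(phantom)
  rows <- list()
  for (st in SITE_LEVELS) {
    target <- locate_target(sites[[st]], phantom,
                            config$target$diameter_mm)
    for (cf in CONFIG_LEVELS) {
      solve_dose <- function(intensity) {
        mon <- build_montage(stimulation_spec(cf, st, intensity), sites,
                             phantom, config$montage$radius_mm,
                             config$montage$ring_mm)
        f <- build_load(sys, mon)
        phi <- solve_potential(sys, f, tol = config$solver$tol,
                               max_iter = config$solver$max_iter)
        J <- compute_current_density(phi, sys)
        dose_summary(J, target)$mean_J
      }
      if (isTRUE(config$solver$independent_solves)) {
        for (int in config$montage$intensities)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = phantom$subject_id, sex = phantom$sex,
            configuration = cf, site = st, intensity = int,
            dose = solve_dose(int))
      } else {
        base <- solve_dose(1.0)
        for (int in config$montage$intensities)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = phantom$subject_id, sex = phantom$sex,
            configuration = cf, site = st, intensity = int,
            dose = base * int)  # exact by solver linearity
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the full study analogue
#'
#' Generates the cohort, forward-models every subject, assembles the
#' 18-rows-per-subject measurement table, fits the main-effects and
#' interaction mixed models, and writes CSV outputs plus a JSON manifest
#' when an output directory is configured.
#'
#' @param config a [default_config()].
#' @param verbose print per-stage progress.
#' @return list: `table`, `anova_main`, `anova_interactions` (or `NULL`
#'   if singular), `cells`, `correlations`, `manifest`.
#' @export
run_full_study <- function(config = default_config(), verbose = TRUE) {
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  spec <- config_cohort_spec(config)
  say("[cohort] generating %d subjects on a %d^3 grid (seed %d)",
      spec$n_subjects, spec$grid_shape[1], spec$seed)
  cohort <- generate_cohort(spec, noise_sd = config$cohort$noise_sd)
  doses <- list()
  for (i in seq_along(cohort)) {
    res <- tryCatch(
      forward_subject(cohort[[i]]$phantom, cohort[[i]]$triplet, config),
      error = function(e) stop("stage forward, subject ",
                               cohort[[i]]$phantom$subject_id, ": ",
                               conditionMessage(e), call. = FALSE))
    doses[[i]] <- res
    say("[forward] %s (%s): median dose %.3g uA/cm^2",
        cohort[[i]]$phantom$subject_id, cohort[[i]]$phantom$sex,
        stats::median(res$dose))
  }
  table <- assemble_measurements(do.call(rbind, doses))
  say("[stats] fitting mixed models on %d rows", nrow(table))
  anova_main <- fit_mixed_model(table, interactions = FALSE)
  anova_int <- tryCatch(fit_mixed_model(table, interactions = TRUE),
                        error = function(e) NULL)
  cells <- summarize_cells(table)
  corr <- cross_site_correlation(table, intensity = 2.0)
  manifest <- list(seed = spec$seed, n_subjects = spec$n_subjects,
                   grid = spec$grid_shape, created = format(t0),
                   elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")),
                   solver = config$solver,
                   resistivity = config$resistivity[c("K", "E", "D")])
  out_dir <- config$output$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(table, file.path(out_dir, "doses.csv"), row.names = FALSE)
    write.csv(cells, file.path(out_dir, "cell_summary.csv"),
              row.names = FALSE)
    write.csv(anova_main$coefficients,
              file.path(out_dir, "anova_main.csv"), row.names = FALSE)
    if (!is.null(anova_int))
      write.csv(anova_int$coefficients,
                file.path(out_dir, "anova_interactions.csv"),
                row.names = FALSE)
    write.csv(corr, file.path(out_dir, "cross_site_correlation.csv"),
              row.names = FALSE)
    if (isTRUE(config$output$write_volumes))
      generate_cohort(spec, noise_sd = config$cohort$noise_sd,
                      out_dir = file.path(out_dir, "volumes"))
    csvs <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
    manifest$file_md5 <- as.list(tools::md5sum(csvs))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  say("[done] %.1f s", manifest$elapsed_s)
  list(table = table, anova_main = anova_main,
       anova_interactions = anova_int, cells = cells,
       correlations = corr, manifest = manifest)
}

#' Run the analytic solver validations
#'
#' Wraps [slab_validation()] and [sphere_validation()] and reports the
#' errors against their thresholds (slab 1e-6 relative on `|J|`; sphere
#' 2% relative RMS on the potential; flux conservation 0.1%).
#'
#' @param sphere_R_mm sphere radius for the series comparison.
#' @param quick smaller slab for fast checks.
#' @return list of class `solver_validation` with `slab`, `sphere`,
#'   `pass` (logical).
#' @export
validate_solver <- function(sphere_R_mm = 25, quick = FALSE) {
  slab <- slab_validation(n = if (quick) 12L else 20L)
  sphere <- sphere_validation(R_mm = sphere_R_mm)
  pass <- slab$J_max_abs_err < 1e-6 && slab$flux_err_rel < 1e-3 &&
    sphere$rms_rel_err < 0.02
  structure(list(slab = slab[c("J_expected", "J_max_abs_err",
                               "phi_linearity", "flux_err_rel")],
                 sphere = sphere, pass = pass),
            class = "solver_validation")
}

#' @export
print.solver_validation <- function(x, ...) {
  cat("Solver validation\n")
  cat(sprintf("  slab |J| rel err:      %.3g (threshold 1e-6)\n",
              x$slab$J_max_abs_err))
  cat(sprintf("  slab flux rel err:     %.3g (threshold 1e-3)\n",
              x$slab$flux_err_rel))
  cat(sprintf("  sphere RMS rel err:    %.3g (threshold 0.02, n = %d)\n",
              x$sphere$rms_rel_err, x$sphere$n_points))
  cat(if (x$pass) "  PASS\n" else "  FAIL\n")
  invisible(x)
}
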