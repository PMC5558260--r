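#' Specify a synthetic head-phantom cohort
#'
#' A `cohort_spec` fixes everything the generator needs: cohort size and sex
#' mix, voxel grid, head scale, per-parameter dispersions and the master
#' seed. Defaults mirror the modelled study population: 12 males and 11
#' females on a 1 mm isotropic grid.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param sex character vector of `"female"`/`"male"`, one per subject.
#' @param grid_shape integer vector of voxel counts per axis (x, y, z).
#' @param voxel_size_mm isotropic voxel edge length in mm (> 0).
#' @param head_scale multiplicative scale on the default head morphology;
#'   `NULL` scales so the head fills the grid (`min(grid_shape) *
#'   voxel_size_mm / 96`).
#' @param variability dispersion/mean settings, see [variability_spec()].
#' @param seed master integer seed; every stochastic draw derives from it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 23L,
                        sex = c(rep("male", 12L), rep("female", 11L)),
                        grid_shape = c(96L, 96L, 96L),
                        voxel_size_mm = 1.0,
                        head_scale = NULL,
                        variability = variability_spec(),
                        seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  sex <- match.arg(sex, c("female", "male"), several.ok = TRUE)
  if (length(sex) != n_subjects)
    stop("sex assignment length (", length(sex), ") must equal n_subjects (",
         n_subjects, ")")
  if (!(voxel_size_mm > 0)) stop("voxel_size_mm must be > 0")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must be three voxel counts >= 8")
  if (is.null(head_scale))
    head_scale <- min(grid_shape) * voxel_size_mm / 100
  structure(list(n_subjects = n_subjects, sex = sex,
                 grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 head_scale = head_scale, variability = variability,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Dispersion and mean settings for phantom generation
#'
#' Sex enters the phantom world only through the skull water-fraction
#' distributions (Beta with the given means and common concentration): a
#' lower water fraction means denser, more resistive bone, so the female
#' default mean (0.08) sits below the male default (0.15). The frontal
#' skull sector is multiplied by `frontal_modifier_mean` (< 1, i.e. denser
#' frontal bone) with a per-subject log-normal jitter. Setting all `cv`
#' values to 0 and `*_kappa` to `Inf` makes same-sex subjects identical.
#'
#' @param radius_cv coefficient of variation of shell radii/thicknesses.
#' @param skull_w_female_mean,skull_w_male_mean Beta means of the skull
#'   water fraction by sex.
#' @param skull_w_kappa Beta concentration (a+b) of the skull draw; `Inf`
#'   collapses the draw to its mean.
#' @param scalp_w_mean,brain_w_mean Beta means for scalp and brain water.
#' @param tissue_w_kappa Beta concentration for scalp/brain draws.
#' @param csf_w,neck_w fixed water fractions for CSF and the neck stub.
#' @param frontal_modifier_mean mean multiplicative modifier (< 1) on skull
#'   water in the frontal sector.
#' @param frontal_modifier_cv log-normal cv of the frontal modifier.
#' @return a list of class `variability_spec`.
#' @export
variability_spec <- function(radius_cv = 0.04,
                             skull_w_female_mean = 0.08,
                             skull_w_male_mean = 0.15,
                             skull_w_kappa = 60,
                             scalp_w_mean = 0.70,
                             brain_w_mean = 0.80,
                             tissue_w_kappa = 4000,
                             csf_w = 1.0,
                             neck_w = 0.70,
                             frontal_modifier_mean = 0.7,
                             frontal_modifier_cv = 0.12) {
  structure(as.list(environment()), class = "variability_spec")
}

rbeta_mean <- function(n, mean, kappa) {
  if (!is.finite(kappa)) return(rep(mean, n))
  stats::rbeta(n, mean * kappa, (1 - mean) * kappa)
}

# baseline morphology (mm) at head_scale = 1; nesting is structural:
# radii are built outer-in from strictly positive thicknesses
BASE_MORPH <- list(scalp_radii = c(36, 42, 34),
                   scalp_thick = 6, skull_thick = 7, csf_thick = 2.5,
                   neck_radius = 12)

#' Draw per-subject morphology parameters
#'
#' Deterministic given `(spec$seed, subject_index)`. Shell radii are nested
#' by construction (outer radii minus jittered positive thicknesses); draws
#' violating nesting or water-fraction bounds are resampled a bounded number
#' of times before failing.
#'
#' @param spec a [cohort_spec()].
#' @param subject_index 1-based subject index (`<= spec$n_subjects`).
#' @return an object of class `morphology_params`.
#' @export
sample_morphology <- function(spec, subject_index) {
  stopifnot(inherits(spec, "cohort_spec"))
  subject_index <- as.integer(subject_index)
  if (subject_index < 1L || subject_index > spec$n_subjects)
    stop("subject_index out of range")
  v <- spec$variability
  sx <- spec$sex[subject_index]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(spec$seed, subject_index))
  for (attempt in seq_len(25L)) {
    # bounded anthropometric jitter: +/- 2.5 sd keeps heads inside the grid
    jit <- function(x) {
      z <- stats::rnorm(length(x), 0, v$radius_cv)
      x * exp(pmin(pmax(z, -2.5 * v$radius_cv), 2.5 * v$radius_cv))
    }
    s <- spec$head_scale
    scalp <- jit(BASE_MORPH$scalp_radii * s)
    th <- c(jit(BASE_MORPH$scalp_thick * s), jit(BASE_MORPH$skull_thick * s),
            jit(BASE_MORPH$csf_thick * s))
    skull <- scalp - th[1]
    csf <- skull - th[2]
    brain <- csf - th[3]
    skull_mean <- if (sx == "female") v$skull_w_female_mean else
      v$skull_w_male_mean
    skull_w <- rbeta_mean(1L, skull_mean, v$skull_w_kappa)
    scalp_w <- rbeta_mean(1L, v$scalp_w_mean, v$tissue_w_kappa)
    brain_w <- rbeta_mean(1L, v$brain_w_mean, v$tissue_w_kappa)
    fmod <- v$frontal_modifier_mean *
      exp(if (v$frontal_modifier_cv > 0)
        stats::rnorm(1L, 0, v$frontal_modifier_cv) else 0)
    m <- structure(list(radii_scalp = scalp, radii_skull = skull,
                        radii_csf = csf, radii_brain = brain,
                        skull_water_fraction_base = skull_w,
                        frontal_density_modifier = min(fmod, 0.99),
                        scalp_w = scalp_w, brain_w = brain_w,
                        csf_w = v$csf_w, neck_w = v$neck_w,
                        neck_radius_mm = BASE_MORPH$neck_radius * s),
                   class = "morphology_params")
    if (morphology_valid(m)) return(m)
  }
  stop("could not draw nested morphology for subject ", subject_index,
       " after 25 attempts")
}

morphology_valid <- function(m) {
  all(m$radii_scalp > m$radii_skull) && all(m$radii_skull > m$radii_csf) &&
    all(m$radii_csf > m$radii_brain) && all(m$radii_brain > 2) &&
    all(unlist(m[c("skull_water_fraction_base", "scalp_w", "brain_w",
                   "csf_w", "neck_w")]) >= 0) &&
    all(unlist(m[c("skull_water_fraction_base", "scalp_w", "brain_w",
                   "csf_w", "neck_w")]) <= 1) &&
    m$frontal_density_modifier > 0 && m$frontal_density_modifier < 1
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Voxelize a head phantom from morphology parameters
#'
#' Labels voxel centers by nested-ellipsoid membership (brain, CSF, skull,
#' scalp) plus a cylindrical neck stub reaching the domain floor, and
#' assigns per-tissue water fractions. The frontal skull sector (anterior
#' quarter, y below centre) is multiplied by the frontal density modifier.
#'
#' @param morphology a [sample_morphology()] result.
#' @param spec the [cohort_spec()] providing the grid.
#' @param sex `"female"` or `"male"` (recorded on the phantom).
#' @param subject_id identifier recorded on the phantom.
#' @return an object of class `head_phantom` with elements `label` (integer
#'   array, codes in `tesdose:::TISSUE_CODES`), `water` (double array in
#'   `[0,1]`), `morphology`, `sex`, `subject_id`, `voxel_size_mm`, `center`.
#' @export
build_phantom <- function(morphology, spec, sex = "female",
                          subject_id = "S01") {
  stopifnot(inherits(morphology, "morphology_params"),
            inherits(spec, "cohort_spec"))
  dims <- spec$grid_shape
  h <- spec$voxel_size_mm
  ext <- dims * h
  a <- morphology$radii_scalp
  if (2 * a[1] + 2 * h > ext[1] || 2 * a[2] + 2 * h > ext[2])
    stop("grid too small: scalp ellipsoid (", round(2 * a[1]), " x ",
         round(2 * a[2]), " mm) does not fit in ", ext[1], " x ", ext[2],
         " mm")
  # head centre: lateral/AP centred, top of scalp two voxels below the lid
  cz <- ext[3] - 2 * h - a[3]
  if (cz - a[3] < 4 * h)
    stop("grid too small: no room for the neck stub below the head")
  center <- c(ext[1] / 2, ext[2] / 2, cz)

  x <- (seq_len(dims[1]) - 0.5) * h - center[1]
  y <- (seq_len(dims[2]) - 0.5) * h - center[2]
  z <- (seq_len(dims[3]) - 0.5) * h - center[3]
  # squared normalized radius per shell, built with outer sums
  shell_inside <- function(r) {
    qx <- (x / r[1])^2; qy <- (y / r[2])^2; qz <- (z / r[3])^2
    q <- outer(outer(qx, qy, "+"), qz, "+")
    q <= 1
  }
  in_scalp <- shell_inside(morphology$radii_scalp)
  in_skull <- shell_inside(morphology$radii_skull)
  in_csf <- shell_inside(morphology$radii_csf)
  in_brain <- shell_inside(morphology$radii_brain)

  lab <- array(TISSUE_CODES[["air"]], dims)
  lab[in_scalp] <- TISSUE_CODES[["scalp"]]
  lab[in_skull] <- TISSUE_CODES[["skull"]]
  lab[in_csf] <- TISSUE_CODES[["csf"]]
  lab[in_brain] <- TISSUE_CODES[["brain"]]

  # neck stub: vertical cylinder below the head, down to the domain floor
  rn <- morphology$neck_radius_mm
  in_cyl <- outer(outer((x / rn)^2, (y / rn)^2, "+"), rep(1, dims[3])) <= 1
  below <- outer(outer(rep(TRUE, dims[1]), rep(TRUE, dims[2])),
                 z <= -0.4 * morphology$radii_scalp[3])
  neck <- in_cyl & below & !in_scalp
  lab[neck] <- TISSUE_CODES[["neck"]]

  w <- array(0, dims)
  w[lab == TISSUE_CODES[["scalp"]]] <- morphology$scalp_w
  w[lab == TISSUE_CODES[["csf"]]] <- morphology$csf_w
  w[lab == TISSUE_CODES[["brain"]]] <- morphology$brain_w
  w[lab == TISSUE_CODES[["neck"]]] <- morphology$neck_w
  skull_m <- lab == TISSUE_CODES[["skull"]]
  frontal <- outer(outer(rep(TRUE, dims[1]),
                         y < -0.25 * morphology$radii_skull[2]),
                   rep(TRUE, dims[3]))
  w[skull_m] <- morphology$skull_water_fraction_base
  w[skull_m & frontal] <- morphology$skull_water_fraction_base *
    morphology$frontal_density_modifier

  structure(list(label = lab, water = w, morphology = morphology,
                 sex = sex, subject_id = subject_id,
                 voxel_size_mm = h, center = center),
            class = "head_phantom")
}

#' Simulate a T1/T2/PD intensity triplet from a phantom
#'
#' Forward maps are fixed monotone functions of the water fraction `w`
#' (arbitrary scanner-like gains): PD = 1000 w, T2 = 800 sqrt(w),
#' T1 = 1200 (1 - w) on head voxels and 0 on air. Independent Gaussian
#' noise (relative sd `noise_sd` of each channel gain) is added and
#' truncated at zero. With `noise_sd = 0`, [combine_mri()] recovers `w`
#' exactly.
#'
#' @param phantom a [build_phantom()] result.
#' @param noise_sd relative noise standard deviation (>= 0).
#' @param seed integer seed for the noise draw.
#' @return an object of class `mri_triplet` with arrays `t1`, `t2`, `pd`.
#' @export
simulate_mri_triplet <- function(phantom, noise_sd = 0.02, seed = 1L) {
  stopifnot(inherits(phantom, "head_phantom"), noise_sd >= 0)
  w <- phantom$water
  head <- phantom$label != TISSUE_CODES[["air"]]
  gains <- c(pd = 1000, t2 = 800, t1 = 1200)
  pd <- gains[["pd"]] * w
  t2 <- gains[["t2"]] * sqrt(w)
  t1 <- gains[["t1"]] * (1 - w)
  t1[!head] <- 0
  if (noise_sd > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(derive_seed(seed, 101L))
    n <- length(w)
    pd <- pmax(pd + stats::rnorm(n, 0, noise_sd * gains[["pd"]]), 0)
    t2 <- pmax(t2 + stats::rnorm(n, 0, noise_sd * gains[["t2"]]), 0)
    t1 <- pmax(t1 + stats::rnorm(n, 0, noise_sd * gains[["t1"]]), 0)
    dim(pd) <- dim(t2) <- dim(t1) <- dim(w)
  }
  structure(list(t1 = t1, t2 = t2, pd = pd, gains = gains),
            class = "mri_triplet")
}

#' Generate a full phantom cohort
#'
#' @param spec a [cohort_spec()].
#' @param noise_sd MRI noise level passed to [simulate_mri_triplet()].
#' @param out_dir optional directory; when given, per-subject NIfTI volumes
#'   and a cohort manifest CSV are written there.
#' @param write_nifti write `.nii.gz` volumes when `out_dir` is set.
#' @return a list of `n_subjects` elements, each
#'   `list(phantom, triplet)`, with the manifest data frame attached as
#'   attribute `"manifest"`.
#' @export
generate_cohort <- function(spec, noise_sd = 0.02, out_dir = NULL,
                            write_nifti = !is.null(out_dir)) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- vector("list", spec$n_subjects)
  man <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    res <- tryCatch({
      morph <- sample_morphology(spec, i)
      sid <- sprintf("S%02d", i)
      ph <- build_phantom(morph, spec, sex = spec$sex[i], subject_id = sid)
      tri <- simulate_mri_triplet(ph, noise_sd = noise_sd,
                                  seed = derive_seed(spec$seed, 1000L + i))
      list(phantom = ph, triplet = tri)
    }, error = function(e)
      stop("subject ", i, ": ", conditionMessage(e), call. = FALSE))
    out[[i]] <- res
    m <- res$phantom$morphology
    man[[i]] <- data.frame(subject_id = res$phantom$subject_id,
                           sex = spec$sex[i], seed = spec$seed,
                           skull_w = m$skull_water_fraction_base,
                           frontal_modifier = m$frontal_density_modifier,
                           scalp_w = m$scalp_w, brain_w = m$brain_w,
                           scalp_rx = m$radii_scalp[1],
                           scalp_ry = m$radii_scalp[2],
                           scalp_rz = m$radii_scalp[3])
  }
  manifest <- do.call(rbind, man)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(manifest, file.path(out_dir, "cohort_manifest.csv"),
              row.names = FALSE)
    if (write_nifti) {
      for (i in seq_len(spec$n_subjects)) {
        sid <- out[[i]]$phantom$subject_id
        vx <- spec$voxel_size_mm
        write_nifti(out[[i]]$phantom$water,
                    file.path(out_dir, paste0(sid, "_water.nii.gz")), vx)
        for (ch in c("t1", "t2", "pd"))
          write_nifti(out[[i]]$triplet[[ch]],
                      file.path(out_dir, paste0(sid, "_", ch, ".nii.gz")),
                      vx)
      }
    }
  }
  attr(out, "manifest") <- manifest
  out
}
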