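test_that("morphology draws are deterministic and reject bad shells", {
  spec <- tiny_spec()
  m1 <- sample_morphology(spec, 1L)
  m2 <- sample_morphology(spec, 1L)
  expect_identical(m1, m2)
  m3 <- sample_morphology(spec, 2L)
  expect_false(identical(m1$skull_water_fraction_base,
                         m3$skull_water_fraction_base))
  expect_true(all(m1$radii_scalp > m1$radii_skull))
  expect_true(all(m1$radii_skull > m1$radii_csf))
  expect_true(all(m1$radii_csf > m1$radii_brain))
  expect_error(sample_morphology(spec, 5L), "out of range")
})

test_that("zero dispersion collapses same-sex subjects to one morphology", {
  v0 <- variability_spec(radius_cv = 0, skull_w_kappa = Inf,
                         tissue_w_kappa = Inf, frontal_modifier_cv = 0)
  spec <- cohort_spec(n_subjects = 4L,
                      sex = c("female", "female", "male", "male"),
                      grid_shape = c(48L, 48L, 48L), variability = v0,
                      seed = 9L)
  expect_identical(sample_morphology(spec, 1L), sample_morphology(spec, 2L))
  expect_identical(sample_morphology(spec, 3L), sample_morphology(spec, 4L))
  # sexes still differ through the skull water mean
  expect_lt(sample_morphology(spec, 1L)$skull_water_fraction_base,
            sample_morphology(spec, 3L)$skull_water_fraction_base)
})

test_that("female skull water sits below male over a large cohort", {
  # Monte-Carlo over the configured Beta distributions, 100 per sex
  spec <- cohort_spec(n_subjects = 200L,
                      sex = rep(c("female", "male"), each = 100L),
                      grid_shape = c(48L, 48L, 48L), seed = 17L)
  w <- vapply(seq_len(200L), function(i)
    sample_morphology(spec, i)$skull_water_fraction_base, numeric(1))
  expect_lt(mean(w[1:100]) + 0.02, mean(w[101:200]))
})

test_that("phantom labels partition the grid with nested shells", {
  w <- tiny_world()
  lab <- w$phantom$label
  codes <- tesdose:::TISSUE_CODES
  expect_true(all(lab %in% codes))           # partition: every voxel labeled
  expect_true(all(table(lab) > 0))           # all six classes present
  # ray from the head centre along +x crosses brain->csf->skull->scalp->air
  ctr <- w$phantom$center
  h <- w$phantom$voxel_size_mm
  j <- ceiling(ctr[2] / h); k <- ceiling(ctr[3] / h)
  ray <- lab[ceiling(ctr[1] / h):dim(lab)[1], j, k]
  seen <- rle(as.integer(ray))$values
  expect_identical(seen, unname(codes[c("brain", "csf", "skull", "scalp",
                                        "air")]))
  # water in [0,1], zero exactly on air
  expect_true(all(w$phantom$water >= 0 & w$phantom$water <= 1))
  expect_true(all(w$phantom$water[lab == codes[["air"]]] == 0))
  expect_true(all(w$phantom$water[lab != codes[["air"]]] > 0))
})

test_that("frontal skull sector carries the density modifier exactly", {
  w <- tiny_world()
  ph <- w$phantom
  codes <- tesdose:::TISSUE_CODES
  h <- ph$voxel_size_mm
  idx <- which(ph$label == codes[["skull"]], arr.ind = TRUE)
  y_mm <- (idx[, 2] - 0.5) * h - ph$center[2]
  frontal <- y_mm < -0.25 * ph$morphology$radii_skull[2]
  wv <- ph$water[ph$label == codes[["skull"]]]
  expect_gt(sum(frontal), 50)
  expect_equal(mean(wv[frontal]) / mean(wv[!frontal]),
               ph$morphology$frontal_density_modifier, tolerance = 1e-12)
})

test_that("noiseless triplets round-trip through combine_mri", {
  w <- tiny_world()
  tri <- simulate_mri_triplet(w$phantom, noise_sd = 0)
  v <- combine_mri(tri)
  expect_lt(max(abs(unclass(v) - w$phantom$water)), 1e-10)
  # air voxels are dark in all three channels
  air <- w$phantom$label == tesdose:::TISSUE_CODES[["air"]]
  expect_equal(max(tri$pd[air]), 0)
  expect_equal(max(tri$t2[air]), 0)
  expect_equal(max(tri$t1[air]), 0)
})

test_that("noise is seeded and additive over a fixed clean component", {
  w <- tiny_world()
  clean <- simulate_mri_triplet(w$phantom, noise_sd = 0)
  a <- simulate_mri_triplet(w$phantom, noise_sd = 0.05, seed = 1L)
  b <- simulate_mri_triplet(w$phantom, noise_sd = 0.05, seed = 2L)
  a2 <- simulate_mri_triplet(w$phantom, noise_sd = 0.05, seed = 1L)
  expect_identical(a$pd, a2$pd)            # same seed reproduces
  expect_false(identical(a$pd, b$pd))      # different seed differs
  # on head voxels (far from the zero-truncation) the noise is zero-mean
  # around the shared clean component
  head <- w$phantom$label != tesdose:::TISSUE_CODES[["air"]]
  expect_lt(abs(mean((a$pd - clean$pd)[head])), 2)
  expect_lt(abs(mean(((a$pd - clean$pd) - (b$pd - clean$pd))[head])), 2)
})

test_that("generate_cohort is reproducible and records sexes", {
  spec <- cohort_spec(n_subjects = 3L, sex = c("female", "male", "male"),
                      grid_shape = c(48L, 48L, 48L), seed = 21L)
  co1 <- generate_cohort(spec, noise_sd = 0.02)
  co2 <- generate_cohort(spec, noise_sd = 0.02)
  expect_length(co1, 3L)
  expect_identical(co1[[2]]$phantom$water, co2[[2]]$phantom$water)
  expect_identical(co1[[3]]$triplet$pd, co2[[3]]$triplet$pd)
  expect_identical(vapply(co1, function(s) s$phantom$sex, character(1)),
                   spec$sex)
  man <- attr(co1, "manifest")
  expect_identical(nrow(man), 3L)
  expect_identical(man$sex, spec$sex)
  # single-subject cohort
  spec1 <- cohort_spec(n_subjects = 1L, sex = "female",
                       grid_shape = c(48L, 48L, 48L), seed = 4L)
  expect_length(generate_cohort(spec1, noise_sd = 0), 1L)
})

test_that("default cohort is 12 males and 11 females", {
  spec <- cohort_spec()
  expect_identical(spec$n_subjects, 23L)
  expect_identical(sum(spec$sex == "male"), 12L)
  expect_identical(sum(spec$sex == "female"), 11L)
})

test_that("spec validation catches bad input", {
  expect_error(cohort_spec(n_subjects = 0), "n_subjects")
  expect_error(cohort_spec(n_subjects = 2, sex = "female"), "length")
  expect_error(cohort_spec(voxel_size_mm = 0), "voxel_size_mm")
  spec <- cohort_spec(n_subjects = 1L, sex = "female",
                      grid_shape = c(24L, 24L, 24L), head_scale = 1.5)
  expect_error(build_phantom(sample_morphology(spec, 1L), spec),
               "grid too small")
})
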