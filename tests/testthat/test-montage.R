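test_that("10-20 sites are symmetric, ordered, and on the scalp surface", {
  w <- tiny_world()
  sites <- w$sites
  ph <- w$phantom
  h <- ph$voxel_size_mm
  cx <- ph$center[1] / h + 0.5
  expect_lt(abs(abs(sites$C3$voxel[1] - cx) - abs(sites$C4$voxel[1] - cx)),
            1.5)                                   # mirror within a voxel
  expect_lt(abs(abs(sites$F3$voxel[1] - cx) - abs(sites$F4$voxel[1] - cx)),
            1.5)
  expect_lt(sites$F3$voxel[2], sites$C3$voxel[2])  # F3 anterior (smaller y)
  codes <- tesdose:::TISSUE_CODES
  surf <- tesdose:::surface_mask(ph)
  for (nm in c("C3", "C4", "F3", "F4")) {
    vx <- sites[[nm]]$voxel
    expect_identical(ph$label[vx[1], vx[2], vx[3]],
                     unname(codes[["scalp"]]))
    expect_true(surf[vx[1], vx[2], vx[3]])         # adjacent to air
  }
  expect_identical(sites$neck$voxel[3], 1L)
})

test_that("footprint on a flat patch matches the brute-force node count", {
  ph <- flat_patch_phantom()
  site <- flat_patch_site()
  fp <- electrode_footprint(site, radius_mm = 5, ph)
  # oracle: on a flat patch the surface-graph geodesic has the closed-form
  # octile metric sqrt(2)*min(|dx|,|dy|) + ||dx|-|dy||; enumerate voxels
  # within 5 mm of the centre and the corner nodes of their top faces
  n <- dim(ph$label)[1]
  vox <- expand.grid(i = 1:n, j = 1:n)
  adx <- abs(vox$i - site$voxel[1]); ady <- abs(vox$j - site$voxel[2])
  octile <- sqrt(2) * pmin(adx, ady) + abs(adx - ady)
  keep <- octile <= 5
  oracle_nodes <- unique(unlist(lapply(which(keep), function(r) {
    i <- vox$i[r]; j <- vox$j[r]
    as.vector(outer(c(i, i + 1), (c(j, j + 1) - 1) * (n + 1), "+"))
  })))
  expect_identical(nrow(fp$voxels), sum(keep))
  expect_identical(length(fp$nodes), length(oracle_nodes))
  expect_gte(length(fp$nodes), 60)
  expect_lte(length(fp$nodes), 100)
  # radius below the voxel size is rejected
  expect_error(electrode_footprint(site, radius_mm = 0.5, ph), "radius")
})

test_that("ring montage has quarter-current cathodes 30 mm out", {
  w <- tiny_world()
  mon <- build_montage(stimulation_spec("ring", "C3", 1.0), w$sites,
                       w$phantom)
  cur <- vapply(mon$electrodes, `[[`, numeric(1), "current_mA")
  expect_identical(sum(cur), 0)                    # exact conservation
  expect_equal(cur, c(1.0, rep(-0.25, 4)))
  geo <- vapply(mon$electrodes[-1], function(e) e$site$geodesic_mm,
                numeric(1))
  expect_true(all(abs(geo - 30) <= 2))
  # cathode footprints disjoint from the anode's and from each other
  fps <- lapply(mon$electrodes, function(e) e$footprint$nodes)
  for (a in 1:4) for (b in (a + 1):5)
    expect_length(intersect(fps[[a]], fps[[b]]), 0)
})

test_that("bi-cranial and non-cephalic montages pair the right returns", {
  w <- tiny_world()
  mon <- build_montage(stimulation_spec("bi_cranial", "F3", 2.0), w$sites,
                       w$phantom)
  tab <- montage_table(mon)
  expect_identical(tab$label, c("F3", "F4"))
  expect_equal(tab$current_mA, c(2.0, -2.0))
  mon2 <- build_montage(stimulation_spec("non_cephalic", "C3", 0.5),
                        w$sites, w$phantom)
  tab2 <- montage_table(mon2)
  expect_identical(tab2$label, c("C3", "neck"))
  expect_equal(sum(tab2$current_mA), 0)
  expect_identical(unique(mon2$electrodes[[2]]$footprint$voxels[, 3]), 1L)
})

test_that("the design enumerates 18 montage specs per subject", {
  grid <- expand.grid(configuration = c("ring", "bi_cranial",
                                        "non_cephalic"),
                      site = c("C3", "F3"), intensity = c(0.5, 1, 2),
                      stringsAsFactors = FALSE)
  specs <- Map(stimulation_spec, grid$configuration, grid$site,
               grid$intensity)
  expect_length(specs, 18L)
  expect_error(stimulation_spec("ring", "C3", -1), "intensity")
})
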