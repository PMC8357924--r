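test_that("phantom negative volume has the closed-form value", {
  sp <- phantom_spec(condyle_radius = 6, gap = 2)
  an <- phantom_analytic(sp, "left")
  expect_equal(an$volume, 2 / 3 * pi * (8^3 - 6^3))
  expect_equal(an$area, 2 * pi * 64 + 2 * pi * 36 + pi * (64 - 36))
  # right side scales the gap
  sp2 <- phantom_spec(asymmetry_factor = 1.5)
  expect_equal(phantom_analytic(sp2, "right")$volume, 2 / 3 * pi * (9^3 - 6^3))
})

test_that("phantom construction is deterministic and plateau-structured", {
  sp <- phantom_spec(seed = 5)
  a <- make_joint_phantom(sp, "left")
  b <- make_joint_phantom(sp, "left")
  expect_identical(a$volume$data, b$volume$data)
  # noise-free phantom has exactly the three tissue plateaus
  ph <- fx_joint()
  expect_equal(sort(unique(as.vector(ph$volume$data))),
               c(0.05, 0.35, 0.85))
  # masks disjoint, meshes watertight
  expect_false(any(ph$mc_mask$data & ph$tb_mask$data))
  expect_true(is_watertight(ph$mc_mesh))
  expect_true(is_watertight(ph$tb_mesh))
  expect_gt(ph$analytic_negative_volume, 0)
})

test_that("voxel-counted gap volume matches the closed form at fine spacing", {
  # spacing = gap/8
  sp <- phantom_spec(noise_sd = 0, spacing = 0.25, grid_shape = c(96, 96, 92))
  ph <- make_joint_phantom(sp, "left")
  vox <- sum(ph$gap_mask$data) * 0.25^3
  expect_equal(vox, ph$analytic_negative_volume, tolerance = 0.03)
})

test_that("phantom geometry must fit its grid", {
  expect_error(make_joint_phantom(
    phantom_spec(grid_shape = c(20, 20, 20)), "left"), "does not fit")
  expect_error(phantom_spec(gap = 0), "gap")
  expect_error(phantom_spec(asymmetry_factor = 0), "asymmetry_factor")
  expect_error(phantom_spec(condyle_radius = 2, neck_radius = 3), "exceed")
  expect_error(phantom_spec(slab_thickness = 5), "containment")
})

test_that("head phantoms are mirror-symmetric with per-side boxes", {
  hp <- fx_head()
  d <- dim(hp$volume$data)
  # exact mirror reflections at asymmetry 1
  expect_identical(hp$left$mc_mask$data,
                   hp$right$mc_mask$data[d[1]:1, , ])
  expect_identical(hp$left$tb_mask$data,
                   hp$right$tb_mask$data[d[1]:1, , ])
  # boxes contain all mask voxels of their side and are disjoint in x
  for (side in c("left", "right")) {
    b <- hp$boxes[[side]]
    idx <- which(hp[[side]]$mc_mask$data | hp[[side]]$tb_mask$data,
                 arr.ind = TRUE)
    expect_true(all(idx[, 1] >= b$min_index[1] & idx[, 1] < b$max_index[1]))
    expect_true(all(idx[, 2] >= b$min_index[2] & idx[, 2] < b$max_index[2]))
    expect_true(all(idx[, 3] >= b$min_index[3] & idx[, 3] < b$max_index[3]))
  }
  expect_lte(hp$boxes$left$max_index[1], hp$boxes$right$min_index[1])
  # joints overlapping their halves is a spec error
  expect_error(make_head_phantom(phantom_spec(grid_shape = c(24, 48, 56))),
               "do not fit")
})

test_that("cohorts are reproducible and flag exactly the asymmetric members", {
  r1 <- make_cohort(6, seed = 3, n_asymmetric = 2,
                    asymmetry_range = c(1.3, 1.5))
  r2 <- make_cohort(6, seed = 3, n_asymmetric = 2,
                    asymmetry_range = c(1.3, 1.5))
  expect_identical(r1$metadata, r2$metadata)
  expect_identical(r1$phantoms[[1]]$volume$data, r2$phantoms[[1]]$volume$data)
  expect_equal(sum(r1$metadata$asymmetric), 2)
  expect_true(all(r1$metadata$asymmetry_factor[r1$metadata$asymmetric] >= 1.3))
  expect_true(all(r1$metadata$asymmetry_factor[!r1$metadata$asymmetric] == 1))
  # degenerate ranges give identical parameters up to the noise realization
  r3 <- make_cohort(3, spec_ranges = list(gap = 2.2), seed = 1)
  expect_true(all(r3$metadata$gap == 2.2))
  expect_error(make_cohort(0), "n must be")
  expect_error(make_cohort(3, spec_ranges = list(gap = c(3, 2))), "bad range")
})

test_that("phantoms serialize to NIfTI + STL + JSON", {
  ph <- fx_joint()
  d <- file.path(tempdir(), "phantom_out")
  write_phantom(ph, d)
  expect_true(file.exists(file.path(d, "volume.nii.gz")))
  expect_true(file.exists(file.path(d, "mc_mesh.stl")))
  meta <- jsonlite::read_json(file.path(d, "metadata.json"))
  expect_equal(meta$analytic_negative_volume, ph$analytic_negative_volume)
})
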