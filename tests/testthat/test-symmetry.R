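test_that("Hausdorff distance matches its definition", {
  A <- matrix(c(0, 0, 0), 1, 3)
  expect_equal(hausdorff_distance(A, A), 0)
  expect_equal(hausdorff_distance(A, matrix(c(3, 0, 0), 1, 3)), 3)
  set.seed(6)
  B <- matrix(rnorm(300), ncol = 3)
  expect_equal(hausdorff_distance(B, B), 0)
  expect_error(hausdorff_distance(matrix(numeric(0), 0, 3), B), "empty")
})

test_that("Hausdorff equals brute force and behaves as a metric", {
  set.seed(17)
  for (i in 1:5) {
    A <- matrix(rnorm(150), ncol = 3)
    B <- matrix(rnorm(180), ncol = 3)
    C <- matrix(rnorm(120), ncol = 3)
    hab <- hausdorff_distance(A, B)
    expect_equal(hab, hausdorff_oracle(A, B), tolerance = 1e-14)
    # symmetry and identity
    expect_equal(hausdorff_distance(B, A), hab)
    expect_equal(hausdorff_distance(A, A), 0)
    # triangle inequality
    expect_lte(hab, hausdorff_distance(A, C) + hausdorff_distance(C, B) + 1e-12)
    # invariance under a common rigid motion
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    t <- rnorm(3)
    expect_equal(hausdorff_distance(A %*% R + rep(t, each = nrow(A)),
                                    B %*% R + rep(t, each = nrow(B))),
                 hab, tolerance = 1e-9)
  }
})

test_that("surface ratio is max/min, symmetric, scale-covariant", {
  expect_equal(surface_ratio(10, 10), 1)
  # spheres of radii r and 2r: areas scale as r^2 -> ratio 4
  expect_equal(surface_ratio(4 * pi * 1^2, 4 * pi * 2^2), 4)
  expect_equal(surface_ratio(3, 7), surface_ratio(7, 3))
  expect_gte(surface_ratio(runif(1, 1, 9), runif(1, 1, 9)), 1)
  expect_error(surface_ratio(0, 1), "positive")
  # uniformly scaling one mesh by s multiplies S_LR by s^2
  s1 <- negvol:::icosphere(1, c(0, 0, 0), 2)
  s2 <- transform_mesh(s1, diag(3) * 1.3)
  a1 <- mesh_measures(s1)$area; a2 <- mesh_measures(s2)$area
  expect_equal(surface_ratio(a1, a2), 1.3^2, tolerance = 1e-9)
})

test_that("mirroring is an involution and aligns symmetric pairs", {
  s <- negvol:::icosphere(1.5, c(3, 0.5, -1), 3)
  plane <- list(point = c(0, 0, 0), normal = c(1, 0, 0))
  m1 <- mirror_align(s, plane)
  m2 <- mirror_align(m1, plane)
  expect_equal(m2$vertices, s$vertices, tolerance = 1e-12)
  expect_true(is_watertight(m1))
  expect_gt(mesh_measures(m1)$volume, 0)  # orientation preserved
})

test_that("symmetric phantom pairs score S_LR ~ 1 and small H_LR", {
  sym <- fx_sym()
  rep <- sym$report; nvl <- sym$nvl
  expect_lt(abs(rep$S_LR - 1), 0.05)
  # mirrored negative volumes nearly coincide: H_LR below twice the typical
  # mesh edge length
  edge <- stats::median(sqrt(rowSums((
    nvl$mesh$vertices[nvl$mesh$faces[, 1], ] -
      nvl$mesh$vertices[nvl$mesh$faces[, 2], ])^2)))
  expect_lt(rep$H_LR, max(2 * edge, 1))
  expect_false(rep$asymmetric)
  # report serializes
  f <- tempfile(fileext = ".json")
  write_symmetry_report(rep, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$S_LR, rep$S_LR)
  expect_true(all(c("H_LR", "S_L", "S_R", "V_L", "V_R") %in% names(j)))
  row <- symmetry_report_row(rep)
  expect_equal(nrow(row), 1)
})

test_that("an asymmetric joint scores strictly larger S_LR and H_LR", {
  hp2 <- make_head_phantom(phantom_spec(noise_sd = 0,
                                        grid_shape = c(52, 52, 56),
                                        asymmetry_factor = 1.2))
  p <- inflation_params(step = 0.24, max_iters = 16, laplacian_weight = 0.2,
                        sdf_resolution = 96)
  nvl <- negative_volume(hp2$left$mc_mesh, hp2$left$tb_mesh,
                         hp2$left$clip_plane, p, resolution = 96)
  nvr <- negative_volume(hp2$right$mc_mesh, hp2$right$tb_mesh,
                         hp2$right$clip_plane, p, resolution = 96)
  rep2 <- symmetry_report(nvl$mesh, nvr$mesh, mid_plane = hp2$mid_plane,
                          refine = "centroid", seed = 3,
                          s_lr_flag = 1.05)
  rep1 <- fx_sym()$report
  expect_gt(rep2$S_LR, rep1$S_LR)
  expect_gt(rep2$H_LR, rep1$H_LR)
  # the 1.2-gap pair is flagged at a threshold between the two regimes
  expect_true(rep2$asymmetric)
  # analytic check of the asymmetric surface ratio
  an <- phantom_analytic(hp2$spec, "right")
  al <- phantom_analytic(hp2$spec, "left")
  expect_equal(rep2$S_LR, surface_ratio(al$area, an$area), tolerance = 0.08)
})

test_that("surface sampling draws points on the mesh", {
  s <- negvol:::icosphere(2, c(0, 0, 0), 2)
  set.seed(1)
  pts <- sample_surface(s, 500)
  expect_equal(dim(pts), c(500L, 3L))
  rr <- sqrt(rowSums(pts^2))
  expect_true(all(rr <= 2 + 1e-9))
  expect_gt(mean(rr), 1.9)  # points lie near the sphere surface
})
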