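test_that("vertex normals are radial on spheres and axial on cube faces", {
  s <- negvol:::icosphere(1, c(0, 0, 0), 3)
  n <- vertex_normals(s)
  radial <- s$vertices / sqrt(rowSums(s$vertices^2))
  ang <- acos(pmin(1, rowSums(n * radial))) * 180 / pi
  expect_lt(max(ang), 2)
  # subdivided cube: face-interior vertex normals along +/- axes
  cube <- negvol:::subdivide_once(negvol:::subdivide_once(
    negvol:::box_mesh(c(0, 0, 0), c(2, 2, 2))))
  nc <- vertex_normals(cube)
  interior <- which(cube$vertices[, 3] == 0 &
                      cube$vertices[, 1] > 0.4 & cube$vertices[, 1] < 1.6 &
                      cube$vertices[, 2] > 0.4 & cube$vertices[, 2] < 1.6)
  expect_true(length(interior) > 0)
  for (i in interior) expect_equal(nc[i, ], c(0, 0, -1), tolerance = 1e-12)
  # flipped orientation is an error (or auto-repaired)
  flipped <- nv_mesh(s$vertices, s$faces[, c(1, 3, 2)])
  expect_error(vertex_normals(flipped, reorient = "error"), "inward")
  n2 <- vertex_normals(flipped, reorient = "auto")
  expect_equal(n2, n, tolerance = 1e-12)
})

test_that("unconstrained inflation grows a sphere by step per iteration", {
  s <- negvol:::icosphere(1, c(0, 0, 0), 3)
  p <- inflation_params(step = 0.25, max_iters = 8, laplacian_weight = 0)
  out <- inflate(s, NULL, p)
  rr <- sqrt(rowSums(out$vertices^2))
  expect_equal(mean(rr), 1 + 8 * 0.25, tolerance = 1e-3)
  expect_lt(diff(range(rr)), 0.02)
})

test_that("inflation volume is non-decreasing and respects the bound", {
  s <- negvol:::icosphere(3, c(0, 0, 0), 3)
  outer_s <- negvol:::icosphere(6, c(0, 0, 0), 3)
  inner_s <- negvol:::icosphere(5, c(0, 0, 0), 3)
  hollow <- nv_mesh(
    rbind(outer_s$vertices, inner_s$vertices),
    rbind(outer_s$faces, inner_s$faces[, c(1, 3, 2)] + nrow(outer_s$vertices)))
  p <- inflation_params(step = 0.2, max_iters = 25, laplacian_weight = 0.3,
                        collision_tolerance = 0.05, sdf_resolution = 96)
  out <- inflate(s, hollow, p, trace = TRUE)
  tr <- attr(out, "trace")
  expect_true(all(diff(tr$volume) > -1e-6))
  expect_equal(tail(tr$frozen_fraction, 1), 1)
  rr <- sqrt(rowSums(out$vertices^2))
  # every vertex within step + tolerance of the inner bound radius
  expect_true(all(abs(rr - 5) <= 0.2 + 0.05 + 0.02))
  # starting inside the bound solid is an error
  expect_error(inflate(negvol:::icosphere(5.5, c(0, 0, 0), 2), hollow, p),
               "intersects")
})

test_that("degenerate Laplacian weight is rejected", {
  expect_error(inflation_params(laplacian_weight = 1), "collapses")
  expect_error(inflation_params(step = 0), "step")
  expect_error(inflation_params(max_iters = 0), "max_iters")
})

test_that("plane clipping caps the cut and preserves watertightness", {
  s <- negvol:::icosphere(1, c(0, 0, 0), 4)
  # plane entirely below: unchanged
  same <- clip_neck(s, list(point = c(0, 0, -2), normal = c(0, 0, 1)))
  expect_identical(same$vertices, s$vertices)
  # equator cut: hemisphere within 2%
  h <- clip_neck(s, list(point = c(0, 0, 0), normal = c(0, 0, 1)))
  expect_true(is_watertight(h))
  expect_equal(mesh_measures(h)$volume, 2 / 3 * pi, tolerance = 0.02)
  # watertight for oblique cuts
  for (nrm in list(c(1, 1, 1), c(-1, 0.5, 2))) {
    cl <- clip_neck(s, list(point = c(0.1, -0.05, 0.2), normal = nrm))
    expect_true(is_watertight(cl))
  }
  expect_error(clip_neck(s, list(point = c(0, 0, 2), normal = c(0, 0, 1))),
               "entire mesh")
})

test_that("voxel Booleans recover analytic differences and intersections", {
  s2 <- negvol:::icosphere(2, c(0, 0, 0), 3)
  s1 <- negvol:::icosphere(1, c(0, 0, 0), 3)
  # a \ a is empty
  empty <- boolean_difference(s2, s2, resolution = 64)
  expect_equal(mesh_measures(empty)$volume, 0)
  # concentric shell within 2%
  shell <- boolean_difference(s2, s1, resolution = 128)
  expect_true(is_watertight(shell))
  expect_equal(mesh_measures(shell)$volume, 4 / 3 * pi * (8 - 1),
               tolerance = 0.02)
  # disjoint subtrahend leaves the minuend
  far <- negvol:::icosphere(1, c(10, 0, 0), 3)
  unch <- boolean_difference(s2, far, resolution = 96)
  expect_equal(mesh_measures(unch)$volume, mesh_measures(s2)$volume,
               tolerance = 0.02)
  # vol(a \ b) = vol(a) - vol(a n b) within 1% (offset spheres)
  b <- negvol:::icosphere(1.5, c(1, 0.3, -0.2), 3)
  va <- mesh_measures(boolean_difference(s2, b, resolution = 128))$volume
  vi <- mesh_measures(boolean_intersection(s2, b, resolution = 128))$volume
  expect_equal(va, mesh_measures(s2)$volume - vi,
               tolerance = 0.01)
  expect_error(boolean_difference(nv_mesh(s2$vertices, s2$faces[-1, ]), s1),
               "watertight")
})

test_that("mesh measures match closed forms and reflection invariance", {
  cube <- negvol:::box_mesh(c(0, 0, 0), c(2, 2, 2))
  m <- mesh_measures(cube)
  expect_equal(m$volume, 8)
  expect_equal(m$area, 24)
  s <- negvol:::icosphere(1, c(0, 0, 0), 4)
  ms <- mesh_measures(s)
  expect_equal(ms$volume, 4 * pi / 3, tolerance = 0.01)
  expect_equal(ms$area, 4 * pi, tolerance = 0.01)
  # mirroring changes neither volume nor area
  mir <- transform_mesh(s, diag(c(-1, 1, 1)), c(0, 0, 0))
  expect_equal(mesh_measures(mir)$volume, ms$volume, tolerance = 1e-12)
  expect_equal(mesh_measures(mir)$area, ms$area, tolerance = 1e-12)
  open_mesh <- nv_mesh(cube$vertices, cube$faces[-1, ])
  expect_error(mesh_measures(open_mesh), "watertight")
  expect_equal(mesh_measures(open_mesh, require_watertight = FALSE)$area,
               24 - 2)
})
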