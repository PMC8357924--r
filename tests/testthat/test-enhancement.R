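test_that("the classical route recovers a clean slab-with-socket bone mask", {
  ph <- fx_joint()
  sp <- ph$volume$spacing
  # slab-with-socket only: bone plateau on the ground-truth socket mask
  v <- array(0.35, dim(ph$tb_mask$data))
  v[ph$tb_mask$data] <- 0.85
  v[ph$gap_mask$data] <- 0.05
  vol <- minmax_normalize(nv_volume(v, sp))
  m <- classical_tb_mask(vol)
  expect_gte(dice_coefficient(m, ph$tb_mask), 0.9)
})

test_that("the classical route rejects unstructured noise and flat input", {
  set.seed(9)
  d <- c(32, 32, 32)
  noise <- minmax_normalize(nv_volume(array(stats::rnorm(prod(d), 0.35, 0.03),
                                            d)))
  expect_warning(m <- classical_tb_mask(noise), "empty")
  expect_lt(mean(m$data), 0.05)
  expect_warning(f <- classical_tb_mask(nv_volume(array(0.5, d))), "flat")
  expect_equal(sum(f$data), 0)
})

test_that("the classical route is deterministic", {
  ph <- fx_joint()
  v <- minmax_normalize(ph$volume)
  expect_identical(classical_tb_mask(v)$data, classical_tb_mask(v)$data)
})

test_that("heatmap fusion respects its bounds and monotonicity", {
  set.seed(4)
  d <- c(24, 24, 24)
  classical <- nv_mask(array(runif(prod(d)) > 0.7, d))
  heat <- nv_volume(array(runif(prod(d)), d))
  core <- heat$data >= 0.9
  out <- fuse_with_heatmap(classical, heat, tau = 0.5)
  # core subset of output subset of classical | core
  expect_true(all(!core | out$data))
  expect_true(all(!out$data | (classical$data | core)))
  # limits
  ones <- nv_volume(array(1, d))
  out1 <- fuse_with_heatmap(classical, ones, tau = 0.5)
  expect_identical(out1$data, classical$data | array(TRUE, d))
  zeros <- nv_volume(array(0, d))
  expect_equal(sum(fuse_with_heatmap(classical, zeros, tau = 0.5)$data), 0)
  # raising tau never grows the output
  lo <- fuse_with_heatmap(classical, heat, tau = 0.3)
  hi <- fuse_with_heatmap(classical, heat, tau = 0.7)
  expect_true(all(!hi$data | lo$data))
  expect_error(fuse_with_heatmap(classical, heat, tau = 1.5), "tau")
})

test_that("slice-stack smoothing preserves smooth masks and removes specks", {
  m <- fx_ball_mask(12, 31)
  sm <- smooth_stack(m, radius = 1)
  expect_gte(dice_coefficient(sm, m), 0.98)
  # voxel count changes by less than 10%
  expect_lt(abs(sum(sm$data) / sum(m$data) - 1), 0.1)
  # a single-voxel speck on a smooth surface is removed
  sp <- m
  sp$data[2, 2, 16] <- TRUE
  sm2 <- smooth_stack(sp, radius = 1)
  expect_false(sm2$data[2, 2, 16])
  expect_error(smooth_stack(nv_mask(array(FALSE, c(8, 8, 8)))), "empty")
  expect_error(smooth_stack(m, radius = 20), "larger than slice")
})

test_that("stack interpolation reaches the reconstruction pitch", {
  # reference stack geometry: 116 equidistant sections at 0.4 mm pitch
  d <- c(20, 20, 116)
  m <- array(FALSE, d); m[6:15, 6:15, 20:90] <- TRUE
  msk <- nv_mask(m, c(0.4, 0.4, 0.4))
  out <- smooth_stack(msk, radius = 1, target_pitch = 0.4)
  expect_equal(dim(out$data)[3], 116L)
  # halving the pitch doubles the stack
  out2 <- smooth_stack(msk, radius = 1, target_pitch = 0.2)
  expect_equal(dim(out2$data)[3], 232L)
  expect_equal(out2$spacing[3], 0.2)
  # physical extent preserved within a voxel
  expect_lt(abs(dim(out2$data)[3] * out2$spacing[3] - 116 * 0.4), 0.4)
})
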