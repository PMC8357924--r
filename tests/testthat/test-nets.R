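test_that("all three architectures are fully convolutional with softmax heads", {
  set.seed(3)
  x <- array(runif(16^3), c(16, 16, 16))
  for (arch in c("vnet", "unet3d", "unet3d_attention")) {
    cfg <- network_config(arch, patch_shape = c(16, 16, 16),
                          base_channels = 2, depth = 2)
    mod <- build_model(cfg, seed = 4)
    out <- model_forward(mod, x)
    expect_equal(dim(out$probs), c(16L, 16L, 16L, 2L))
    sums <- out$probs[, , , 1] + out$probs[, , , 2]
    expect_lt(max(abs(sums - 1)), 1e-10)
  }
})

test_that("model building is deterministic in the seed", {
  cfg <- network_config("vnet", c(16, 16, 16), base_channels = 2, depth = 2)
  m1 <- build_model(cfg, seed = 9)
  m2 <- build_model(cfg, seed = 9)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(cfg, seed = 10)
  expect_false(identical(m1$params, m3$params))
})

test_that("patch shape must divide the pooling factor", {
  expect_error(network_config("vnet", patch_shape = c(30, 32, 32), depth = 3),
               "divisible")
  cfg <- network_config("vnet", c(16, 16, 16), base_channels = 2, depth = 2)
  mod <- build_model(cfg, 1)
  expect_error(model_forward(mod, array(0, c(15, 16, 16))), "divisible")
  # fully convolutional: other divisible shapes work
  out <- model_forward(mod, array(0, c(8, 24, 16)))
  expect_equal(dim(out$probs)[1:3], c(8L, 24L, 16L))
})

test_that("analytic FLOPs follow the hand-counted convolution cost", {
  # single 3x3x3 convolution, 1 -> 1 channels, 10^3 input, same padding:
  # 2 * 27 * 1000 multiply-accumulate FLOPs (+ 1000 bias adds)
  nd <- list(op = "conv", k = 3L, cin = 1L, shape = c(10L, 10L, 10L, 1L))
  g <- negvol:::.graph_new()
  x <- negvol:::.graph_add(g, "input", shape0 = c(10L, 10L, 10L, 1L))
  cid <- negvol:::.graph_add(g, "conv", x, k = 3L, cin = 1L, cout = 1L)
  node <- g$nodes[[cid]]
  fl <- prod(node$shape[1:3]) * (2 * node$k^3 * node$cin * node$shape[4])
  expect_equal(fl, 54000)
})

test_that("FLOPs scale with voxel count for fixed channels", {
  cfg1 <- network_config("unet3d", c(16, 16, 16), base_channels = 4, depth = 3)
  cfg2 <- network_config("unet3d", c(32, 32, 32), base_channels = 4, depth = 3)
  cfg3 <- network_config("unet3d", c(32, 16, 16), base_channels = 4, depth = 3)
  expect_equal(count_flops(cfg2) / count_flops(cfg1), 8)
  expect_equal(count_flops(cfg3) / count_flops(cfg1), 2)
  # both counting conventions scale identically; dataflow is cheaper
  expect_lt(count_flops(cfg1, transposed = "dataflow"), count_flops(cfg1))
})

test_that("the attention variant has strictly more parameters", {
  for (d in 2:3) {
    plain <- network_config("unet3d", c(16, 16, 16), base_channels = 4,
                            depth = d)
    att <- network_config("unet3d_attention", c(16, 16, 16),
                          base_channels = 4, depth = d)
    expect_gt(count_params(att), count_params(plain))
  }
})

test_that("checkpoints round-trip through save/load", {
  cfg <- network_config("vnet", c(8, 8, 8), base_channels = 2, depth = 2)
  mod <- build_model(cfg, 1)
  f <- tempfile(fileext = ".rds")
  save_model(mod, f)
  m2 <- load_model(f)
  x <- array(runif(512), c(8, 8, 8))
  expect_identical(model_forward(mod, x)$probs, model_forward(m2, x)$probs)
})
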