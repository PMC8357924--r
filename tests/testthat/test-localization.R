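test_that("minimum-method threshold finds the valley of bimodal data", {
  set.seed(14)
  x <- c(rnorm(4000, 0.1, 0.04), rnorm(4000, 0.9, 0.04))
  tm <- threshold_minimum(x)
  expect_false(tm$unimodal)
  expect_gt(tm$threshold, 0.3)
  expect_lt(tm$threshold, 0.7)
  # brute-force valley scan on the smoothed histogram agrees
  cn <- tm$counts
  peaks <- which(cn > c(-Inf, head(cn, -1)) & cn > c(tail(cn, -1), -Inf))
  expect_equal(length(peaks), 2)
  between <- peaks[1]:peaks[2]
  valley_bin <- between[which.min(cn[between])]
  h <- hist(x, breaks = seq(min(x), max(x), length.out = 257), plot = FALSE)
  expect_equal(tm$threshold, h$mids[valley_bin])
  # a clean bimodal mixture is strongly separated (deep valley)
  expect_gt(tm$mode_separation, 5)
  # constant input has no valley
  expect_true(threshold_minimum(rep(2, 100))$unimodal)
})

test_that("postprocessing thresholds, opens, and removes outlier components", {
  d <- c(32, 32, 8)
  p <- array(0.05, d)
  p[4:12, 4:12, 3:6] <- 0.95          # blob 1
  p[20:28, 20:28, 3:6] <- 0.95        # blob 2
  p[16, 16, 4] <- 0.95                # speck
  pv <- nv_volume(p, c(1, 1, 1))
  m <- postprocess_localization(pv)
  lab <- label_components(m)
  expect_equal(attr(lab, "n"), 2)
  expect_false(m$data[16, 16, 4])
  expect_true(all(m$data[5:11, 5:11, 4]))
  # postprocessed mask is a subset of the raw thresholded mask
  tm <- threshold_minimum(as.vector(p))
  expect_true(all(!m$data | (p > tm$threshold)))
  # all-zero probability: unimodal fallback, empty mask, warnings
  w <- capture_warnings(e <- postprocess_localization(nv_volume(array(0, d))))
  expect_true(any(grepl("unimodal|empty", w)))
  expect_equal(sum(e$data), 0)
  expect_error(postprocess_localization(nv_volume(array(2, d))), "0, 1")
})

test_that("VOI boxes cover each side and mirror each other", {
  hp <- fx_head()
  joint <- nv_mask(hp$left$mc_mask$data | hp$left$tb_mask$data |
                     hp$right$mc_mask$data | hp$right$tb_mask$data,
                   hp$volume$spacing)
  boxes <- extract_voi_boxes(joint, margin = 0.05)
  d <- dim(joint$data)
  for (side in c("left", "right")) {
    idx <- which(hp[[side]]$mc_mask$data | hp[[side]]$tb_mask$data,
                 arr.ind = TRUE)
    b <- boxes[[side]]
    expect_true(all(idx[, 1] >= b$min_index[1] & idx[, 1] < b$max_index[1]))
    expect_true(all(idx[, 3] >= b$min_index[3] & idx[, 3] < b$max_index[3]))
  }
  # mirrored phantom: boxes are mirror images within one voxel
  lb <- boxes$left; rb <- boxes$right
  expect_lte(abs((d[1] + 1 - rb$max_index[1] + 1) - lb$min_index[1]), 1)
  expect_lte(abs((d[1] + 1 - rb$min_index[1] + 1) - lb$max_index[1]), 1)
  # a single blob cannot be split into sides
  single <- nv_mask(array(FALSE, c(20, 20, 20)))
  single$data[8:12, 8:12, 8:12] <- TRUE
  expect_error(extract_voi_boxes(single), "fewer than 2|one body side")
})

test_that("VOI cropping shifts origins, re-embeds, and pads to patch shape", {
  set.seed(2)
  v <- nv_volume(array(rnorm(20^3), c(20, 20, 20)), spacing = c(0.5, 0.5, 0.5))
  b <- bounding_box(c(3, 5, 7), c(11, 13, 15), "left")
  cr <- crop_voi(v, b)
  expect_equal(dim(cr$data), c(8L, 8L, 8L))
  expect_equal(cr$origin, v$origin + c(2, 4, 6) * 0.5)
  # full-grid box is the identity
  full <- bounding_box(c(1, 1, 1), dim(v$data) + 1L, "left")
  expect_identical(crop_voi(v, full)$data, v$data)
  # crop then re-embed equals the source region
  host <- nv_volume(array(0, dim(v$data)), v$spacing)
  back <- negvol:::embed_voi(host, cr, b)
  expect_identical(back$data[3:10, 5:12, 7:14], v$data[3:10, 5:12, 7:14])
  # fixed patch shape by centre padding
  p <- crop_voi(v, b, patch_shape = c(12, 12, 4))
  expect_equal(dim(p$data), c(12L, 12L, 4L))
  expect_error(crop_voi(v, bounding_box(c(1, 1, 1), c(30, 5, 5), "left")),
               "out of volume bounds")
})

test_that("coarse segmentation returns a probability field on the input grid", {
  cfg <- network_config("vnet", c(16, 16, 16), base_channels = 2, depth = 2)
  mod <- build_model(cfg, 1)
  v <- nv_volume(array(runif(16^3), c(16, 16, 16)))
  p <- coarse_segment(v, mod)
  expect_s3_class(p, "nv_volume")
  expect_equal(dim(p$data), dim(v$data))
  expect_gte(min(p$data), 0)
  expect_lte(max(p$data), 1)
})
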