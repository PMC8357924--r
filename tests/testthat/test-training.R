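test_that("Dice and cross-entropy losses match their closed forms", {
  d <- c(4, 4, 1)
  t <- array(0, d); t[1:2] <- 1
  # perfect hard prediction
  expect_lt(dice_loss(t, t), 1e-4)
  # disjoint prediction
  p <- array(0, d); p[3:4] <- 1
  expect_gt(dice_loss(p, t), 0.999)
  # |P| = 2, |T| = 2, overlap 1: 1 - 2/4 = 0.5
  p2 <- array(0, d); p2[2:3] <- 1
  expect_equal(dice_loss(p2, t), 0.5, tolerance = 1e-4)
  # CE closed forms
  perfect <- t
  expect_lt(ce_loss(pmin(pmax(perfect, 1e-12), 1), t), 1e-10)
  uniform <- array(0.5, d)
  expect_equal(ce_loss(uniform, t), log(2))
  # combined with weights (1, 1) is the sum
  expect_equal(combined_loss(p2, t, c(1, 1)),
               dice_loss(p2, t) + ce_loss(p2, t))
  expect_error(combined_loss(p2, t, c(0, 0)), "weights")
  expect_error(dice_loss(array(0, c(2, 2, 2)), t), "shape mismatch")
})

test_that("Dice loss and Dice score are consistent on hard masks", {
  set.seed(8)
  for (i in 1:5) {
    a <- array(runif(8^3) > 0.6, c(8, 8, 8))
    b <- array(runif(8^3) > 0.6, c(8, 8, 8))
    if (!any(a) || !any(b)) next
    m <- evaluate_segmentation(nv_mask(a, c(1, 1, 1)), nv_mask(b, c(1, 1, 1)))
    expect_equal(dice_loss(a * 1.0, b * 1.0) + m$dice_pct / 100, 1,
                 tolerance = 1e-3)
  }
})

test_that("segmentation metrics: identity, shifted ball, closed-form Dice", {
  n <- 24
  x <- seq_len(n) - 10
  ball <- function(cx) {
    d2 <- outer(outer((seq_len(n) - cx)^2, x^2, `+`), x^2, `+`)
    nv_mask(d2 <= 16, c(1, 1, 1))
  }
  a <- ball(10)
  m <- evaluate_segmentation(a, a)
  expect_equal(m$dice_pct, 100)
  expect_equal(m$hd_mm, 0)
  # ball shifted by 3 voxels at spacing 1 mm -> HD 3 mm
  b <- ball(13)
  expect_equal(evaluate_segmentation(a, b)$hd_mm, 3)
  # |P| = |T| = 100, overlap 80 -> 80%
  p <- array(0, c(20, 20, 1)); p[1:100] <- 1
  t <- array(0, c(20, 20, 1)); t[21:120] <- 1
  expect_equal(evaluate_segmentation(p, t)$dice_pct, 80)
  expect_error(evaluate_segmentation(array(0, c(4, 4, 4)),
                                     array(0, c(4, 4, 4))), "both masks empty")
})

test_that("Hausdorff on masks equals the brute-force all-pairs computation", {
  set.seed(21)
  for (i in 1:4) {
    a <- array(runif(12^3) > 0.9, c(12, 12, 12))
    b <- array(runif(12^3) > 0.9, c(12, 12, 12))
    if (!any(a) || !any(b)) next
    sa <- negvol:::.surface_voxels(a); sb <- negvol:::.surface_voxels(b)
    A <- which(sa, arr.ind = TRUE) * 1.0
    B <- which(sb, arr.ind = TRUE) * 1.0
    expect_equal(negvol:::.hausdorff_masks(a, b, c(1, 1, 1)),
                 hausdorff_oracle(A, B), tolerance = 1e-12)
  }
})

test_that("augmentation is seeded, flips are involutions, counts conserved", {
  ph <- fx_joint()
  b <- bounding_box(c(9, 9, 9), c(41, 41, 41), "left")
  img <- minmax_normalize(crop_voi(ph$volume, b))
  msk <- crop_voi(ph$mc_mask, b)
  a1 <- augment(img, msk, seed = 5)
  a2 <- augment(img, msk, seed = 5)
  expect_identical(a1$image$data, a2$image$data)
  expect_identical(a1$mask$data, a2$mask$data)
  # left-right flip is an involution
  expect_identical(flip_lr(flip_lr(img))$data, img$data)
  # flip + integer translation conserve mask voxels (object off the border)
  pars <- augment_params(rotation_deg = 0, flip_prob = 1,
                         contrast_gamma = c(1, 1), translation_vox = 2,
                         elastic_alpha = 0)
  a3 <- augment(img, msk, seed = 2, params = pars)
  expect_equal(sum(a3$mask$data), sum(msk$data))
})

test_that("training reduces the loss and is reproducible; 0 epochs is identity", {
  ph <- fx_joint()
  b <- bounding_box(c(13, 13, 9), c(37, 37, 33), "left")
  smp <- list(image = minmax_normalize(crop_voi(ph$volume, b)),
              mask = crop_voi(ph$mc_mask, b))
  cfg <- network_config("vnet", c(24, 24, 24), base_channels = 2, depth = 2)
  model <- build_model(cfg, seed = 1)
  tc0 <- train_config(epochs = 0)
  fit0 <- train_model(model, list(smp), tc0)
  expect_identical(fit0$model$params, model$params)
  tc <- train_config(learning_rate = 3e-3, weight_decay = 1e-4, epochs = 8,
                     seed = 2)
  fit1 <- train_model(model, list(smp), tc)
  fit2 <- train_model(model, list(smp), tc)
  expect_identical(fit1$history, fit2$history)
  expect_lt(tail(fit1$history$loss, 1), fit1$history$loss[1])
})

test_that("backpropagated gradients match finite differences", {
  set.seed(12)
  x <- array(runif(8^3), c(8, 8, 8))
  t <- array(as.numeric(runif(8^3) > 0.5), c(8, 8, 8))
  for (arch in c("vnet", "unet3d_attention")) {
    cfg <- network_config(arch, c(8, 8, 8), base_channels = 2, depth = 2)
    mod <- build_model(cfg, seed = 2)
    fw <- model_forward(mod, x, keep_cache = TRUE)
    gr <- negvol:::model_backward(mod, fw$cache,
                                  negvol:::.loss_grad_logits(fw$probs, t))
    for (nm in sample(names(mod$params), 3)) {
      i <- sample(length(mod$params[[nm]]), 1)
      eps <- 1e-5
      m2 <- mod
      m2$params[[nm]][i] <- mod$params[[nm]][i] + eps
      l1 <- combined_loss(model_forward(m2, x)$probs, t)
      m2$params[[nm]][i] <- mod$params[[nm]][i] - eps
      l2 <- combined_loss(model_forward(m2, x)$probs, t)
      fd <- (l1 - l2) / (2 * eps)
      expect_equal(gr[[nm]][i], fd, tolerance = 1e-4)
    }
  }
})

test_that("cross-validation partitions patients, never patches", {
  set.seed(30)
  mk_sample <- function() {
    img <- array(runif(8^3), c(8, 8, 8))
    msk <- array(FALSE, c(8, 8, 8)); msk[3:6, 3:6, 3:6] <- TRUE
    list(image = nv_volume(img), mask = nv_mask(msk))
  }
  cohort <- lapply(1:5, function(i)
    list(id = paste0("p", i), samples = list(mk_sample(), mk_sample())))
  mcfg <- network_config("vnet", c(8, 8, 8), base_channels = 2, depth = 2)
  tcfg <- train_config(epochs = 1, learning_rate = 1e-3, folds = 5, seed = 4)
  cv <- cross_validate(cohort, mcfg, tcfg)
  # each patient in exactly one validation fold
  expect_equal(sort(cv$folds$patient), paste0("p", 1:5))
  expect_equal(length(unique(cv$folds$fold)), 5)
  # both joints of a patient share the fold
  per_pat <- tapply(cv$metrics$fold, cv$metrics$patient,
                    function(f) length(unique(f)))
  expect_true(all(per_pat == 1))
  expect_equal(nrow(cv$metrics), 10)
  expect_equal(cv$summary$score, c("dice_pct", "ce", "hd_mm"))
  expect_error(cross_validate(cohort[1:3], mcfg, tcfg), "fewer patients")
})
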