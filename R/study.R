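# Scaled-down phantom study: generate a cohort, train small segmentation
# networks on ground-truth patches, run the full pipeline on every head and
# compare the recovered negative volumes and symmetry metrics with the
# phantoms' analytic values.

#' Extract a fixed-shape training patch for one joint of a head phantom
#'
#' Crops the head volume and the requested ground-truth mask to a
#' `patch_shape` window centred on the joint's (condyle + socket) mass
#' centroid; the image is re-normalized.
#'
#' @param hp a head phantom from [make_head_phantom].
#' @param side `"left"` or `"right"`.
#' @param target `"mc"` (condyle) or `"tb"` (socket bone).
#' @param patch_shape patch size (voxels).
#' @return list with `image` ([nv_volume]) and `mask` ([nv_mask]).
#' @export
phantom_patch <- function(hp, side = c("left", "right"),
                          target = c("mc", "tb"), patch_shape = c(32, 32, 32)) {
  side <- match.arg(side); target <- match.arg(target)
  joint <- hp[[side]]$mc_mask$data | hp[[side]]$tb_mask$data
  cent <- colMeans(which(joint, arr.ind = TRUE))
  b <- centered_box(cent, patch_shape, dim(hp$volume$data), side)
  img <- minmax_normalize(crop_voi(hp$volume, b))
  msk <- crop_voi(hp[[side]][[paste0(target, "_mask")]], b)
  list(image = img, mask = msk)
}

#' Train condyle and localization models on a phantom cohort
#'
#' The condyle model is a small V-Net trained on per-joint patches of the
#' training patients; the localization model is the same architecture
#' trained on whole heads resampled to a coarse grid with the combined
#' (condyle + socket) mask as target.
#'
#' @param cohort result of [make_cohort].
#' @param train_ids patient indices used for training.
#' @param patch_shape condyle patch size.
#' @param loc_shape localization grid.
#' @param base_channels,depth V-Net size.
#' @param epochs_mc,epochs_loc training epochs.
#' @param learning_rate,weight_decay optimizer settings.
#' @param seed RNG seed.
#' @return list with `mc_model`, `loc_model` and both training histories.
#' @export
train_phantom_models <- function(cohort, train_ids,
                                 patch_shape = c(32, 32, 32),
                                 loc_shape = c(32, 32, 32),
                                 base_channels = 4, depth = 3,
                                 epochs_mc = 30, epochs_loc = 14,
                                 learning_rate = 3e-3, weight_decay = 1e-4,
                                 seed = 1) {
  phs <- cohort$phantoms
  mc_set <- list()
  for (i in train_ids) for (side in c("left", "right"))
    mc_set[[length(mc_set) + 1]] <- phantom_patch(phs[[i]], side, "mc",
                                                  patch_shape)
  mc_cfg <- network_config("vnet", patch_shape = patch_shape,
                           base_channels = base_channels, depth = depth)
  # mild translation/flip/contrast augmentation makes the network tolerate
  # the few-voxel centring jitter of pipeline VOIs; integer translations and
  # flips transform the target masks exactly (no boundary label noise)
  aug <- augment_params(rotation_deg = 0, flip_prob = 0.5,
                        contrast_gamma = c(0.9, 1.1), translation_vox = 3,
                        elastic_alpha = 0)
  mc_fit <- train_model(build_model(mc_cfg, seed = seed), mc_set,
                        train_config(learning_rate = learning_rate,
                                     weight_decay = weight_decay,
                                     epochs = epochs_mc, batch_size = 2,
                                     seed = seed, augment = TRUE,
                                     augment_params = aug))
  loc_set <- lapply(train_ids, function(i) {
    hp <- phs[[i]]
    img <- resample(minmax_normalize(hp$volume), loc_shape)
    joint <- hp$left$mc_mask$data | hp$left$tb_mask$data |
      hp$right$mc_mask$data | hp$right$tb_mask$data
    msk <- resample(nv_volume(joint * 1.0, hp$volume$spacing), loc_shape)
    list(image = minmax_normalize(img),
         mask = nv_mask(msk$data >= 0.5, msk$spacing, msk$origin))
  })
  loc_cfg <- network_config("vnet", patch_shape = loc_shape,
                            base_channels = base_channels, depth = depth)
  loc_fit <- train_model(build_model(loc_cfg, seed = seed + 1), loc_set,
                         train_config(learning_rate = learning_rate,
                                      weight_decay = weight_decay,
                                      epochs = epochs_loc, batch_size = 2,
                                      seed = seed + 1))
  list(mc_model = mc_fit$model, loc_model = loc_fit$model,
       mc_history = mc_fit$history, loc_history = loc_fit$history)
}

#' Scaled-down end-to-end phantom study
#'
#' Generates a seeded phantom cohort (a fraction of it with asymmetric right
#' joints), trains the models on the training patients, evaluates held-out
#' condyle segmentation, runs the full pipeline on every head, and compares
#' the pipeline's symmetry metrics with the analytic geometry.  The
#' asymmetry flag threshold is derived from the cohort's own analytic
#' surface ratios (midpoint between the symmetric value 1 and the smallest
#' asymmetric analytic S_LR) unless given.
#'
#' @param n cohort size.
#' @param seed study seed.
#' @param n_asymmetric number of asymmetric phantoms.
#' @param asymmetry_range right-gap factor range for those.
#' @param n_train patients used for training (the rest are held out).
#' @param grid_shape per-joint grid of the phantoms.
#' @param epochs_mc,epochs_loc training epochs.
#' @param s_lr_flag asymmetry flag threshold; `NULL` derives it from the
#'   analytic geometry.
#' @param verbose print progress.
#' @return list with `metadata` (cohort tibble + pipeline columns),
#'   `holdout` (per-joint held-out segmentation metrics), `models`,
#'   and `s_lr_flag`.
#' @export
phantom_study <- function(n = 10, seed = 11, n_asymmetric = 3,
                          asymmetry_range = c(1.25, 1.35), n_train = 7,
                          grid_shape = c(52, 52, 56),
                          epochs_mc = 30, epochs_loc = 14,
                          s_lr_flag = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  coh <- make_cohort(n, spec_ranges = list(grid_shape = grid_shape),
                     seed = seed, n_asymmetric = n_asymmetric,
                     asymmetry_range = asymmetry_range)
  md <- coh$metadata
  if (is.null(s_lr_flag)) {
    s_asym <- md$s_lr_analytic[md$asymmetric]
    s_lr_flag <- if (length(s_asym) > 0) (1 + min(s_asym)) / 2 else 1.15
  }
  say("training on patients 1..%d (flag S_LR > %.3f)", n_train, s_lr_flag)
  models <- train_phantom_models(coh, seq_len(n_train),
                                 epochs_mc = epochs_mc,
                                 epochs_loc = epochs_loc, seed = seed)
  hold_ids <- setdiff(seq_len(n), seq_len(n_train))
  hold <- list()
  for (i in hold_ids) for (side in c("left", "right")) {
    s <- phantom_patch(coh$phantoms[[i]], side, "mc")
    p <- predict_volume(models$mc_model, s$image)
    m <- if (any(p > 0.5)) evaluate_segmentation(p, s$mask)
         else list(dice_pct = 0, ce = NA_real_, hd_mm = Inf)
    hold[[length(hold) + 1]] <- tibble::tibble(
      id = i, side = side, dice_pct = m$dice_pct, ce = m$ce, hd_mm = m$hd_mm)
  }
  holdout <- do.call(rbind, hold)
  say("held-out condyle Dice: %.1f%%", mean(holdout$dice_pct))
  res <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- coh$phantoms[[i]]$spec
    gap_max <- sp$gap * max(1, sp$asymmetry_factor)
    step <- gap_max / 10
    cfg <- pipeline_config(
      input = list(object = coh$phantoms[[i]]),
      localization = list(resolution = c(32, 32, 32), open_radius = 2,
                          margin = 0),
      segmentation = list(patch_shape = c(32, 32, 32),
                          voi_shape = c(48, 48, 48)),
      inflation = list(step = step, max_iters = 22,
                       sdf_resolution = 96, resolution = 112),
      symmetry = list(s_lr_flag = s_lr_flag),
      models = list(localization = models$loc_model, mc = models$mc_model),
      seed = seed + i)
    r <- run_pipeline(cfg)
    res[[i]] <- tibble::tibble(
      s_lr_pipeline = r$report$S_LR, h_lr_pipeline = r$report$H_LR,
      v_left_pipeline = r$report$V_L, v_right_pipeline = r$report$V_R,
      flagged = r$report$asymmetric)
    say("phantom %d: S_LR %.3f (analytic %.3f) flagged %s", i,
        r$report$S_LR, md$s_lr_analytic[i], r$report$asymmetric)
  }
  list(metadata = cbind(md, do.call(rbind, res)), holdout = holdout,
       models = models, s_lr_flag = s_lr_flag)
}
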