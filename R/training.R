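# Losses (soft Dice, cross-entropy, their linear combination), segmentation
# metrics (Dice %, CE, symmetric Hausdorff distance in mm), on-the-fly
# augmentation, the Adam patch-training loop and patient-wise k-fold
# cross-validation.

.DICE_EPS <- 1e-5

# coerce prediction input to a foreground-probability array: accepts a 3D
# probability array, a (X,Y,Z,C) softmax output (foreground = last class),
# or an nv_mask / nv_volume
.fg_prob <- function(pred) {
  if (inherits(pred, "nv_volume")) pred <- pred$data
  if (is.logical(pred)) pred <- pred * 1.0
  nd <- length(dim(pred))
  if (nd == 4L) pred <- pred[, , , dim(pred)[4]]
  pred
}

.mask_arr <- function(target) {
  if (inherits(target, "nv_volume")) target <- target$data
  target * 1.0
}

#' Soft Dice loss
#'
#' `1 - (2 |P ∩ T| + eps) / (|P| + |T| + eps)` with a soft intersection over
#' the foreground probability (smoothing `eps = 1e-5`).
#'
#' @param pred foreground probabilities: 3D array, `(X,Y,Z,classes)` softmax
#'   output (last class = foreground), or an [nv_volume]/[nv_mask].
#' @param target binary mask (array or [nv_mask]) of the same spatial shape.
#' @return numeric loss in \[0, 1\].
#' @export
dice_loss <- function(pred, target) {
  p <- .fg_prob(pred); t <- .mask_arr(target)
  if (!identical(dim(p), dim(t))) stop("shape mismatch", call. = FALSE)
  inter <- sum(p * t)
  1 - (2 * inter + .DICE_EPS) / (sum(p) + sum(t) + .DICE_EPS)
}

#' Cross-entropy loss
#'
#' Mean voxelwise negative log-probability of the true class.  For binary
#' problems `pred` may be the foreground probability; probabilities are
#' clamped away from 0.
#'
#' @inheritParams dice_loss
#' @return numeric loss >= 0.
#' @export
ce_loss <- function(pred, target) {
  t <- .mask_arr(target)
  if (inherits(pred, "nv_volume")) pred <- pred$data
  if (length(dim(pred)) == 4L) {
    C <- dim(pred)[4]
    s <- array(0, dim(pred)[1:3])
    for (c in seq_len(C)) s <- s + pred[, , , c]
    if (max(abs(s - 1)) > 1e-4)
      stop("class probabilities must sum to 1 at every voxel", call. = FALSE)
    pt <- pred[, , , C] * t + pred[, , , 1] * (1 - t)
  } else {
    if (min(pred) < -1e-9 || max(pred) > 1 + 1e-9)
      stop("probabilities must lie in [0, 1]", call. = FALSE)
    pt <- pred * t + (1 - pred) * (1 - t)
  }
  if (!identical(dim(pt), dim(t))) stop("shape mismatch", call. = FALSE)
  -mean(log(pmax(pt, 1e-12)))
}

#' Linear combination of Dice and cross-entropy losses
#'
#' @inheritParams dice_loss
#' @param weights length-2 non-negative weights `(dice, ce)`, not both zero.
#' @return numeric loss.
#' @export
combined_loss <- function(pred, target, weights = c(1, 1)) {
  if (length(weights) != 2 || any(weights < 0) || sum(weights) == 0)
    stop("weights must be 2 non-negative numbers, not both zero", call. = FALSE)
  weights[1] * dice_loss(pred, target) + weights[2] * ce_loss(pred, target)
}

# gradient of the combined loss w.r.t. logits, for a 2..C class softmax
# output; target is binary (foreground = last class)
.loss_grad_logits <- function(probs, target, weights = c(1, 1)) {
  d <- dim(probs); C <- d[4]
  t <- .mask_arr(target)
  n <- prod(d[1:3])
  # CE: dL/dlogit = (p - onehot)/n
  onehot <- array(0, d)
  onehot[, , , 1] <- 1 - t
  onehot[, , , C] <- onehot[, , , C] + t
  g <- weights[2] * (probs - onehot) / n
  # Dice on the foreground channel, chained through the softmax
  p <- probs[, , , C]
  denom <- sum(p) + sum(t) + .DICE_EPS
  num <- 2 * sum(p * t) + .DICE_EPS
  dLdp <- -(2 * t * denom - num) / denom^2
  gd <- array(0, d)
  gd[, , , C] <- dLdp
  # softmax chain: dlogit_c = p_c (g_c - sum_k g_k p_k)
  dot <- array(0, d[1:3])
  for (c in seq_len(C)) dot <- dot + gd[, , , c] * probs[, , , c]
  sm <- probs * (gd - as.vector(dot))
  g + weights[1] * sm
}

#' Segmentation quality metrics
#'
#' Dice score in percent, voxelwise cross-entropy, and the symmetric
#' Hausdorff distance (mm) between the surface voxels of the two masks
#' (exact Euclidean, via the distance transform).
#'
#' @param pred predicted [nv_mask] (or probability volume; thresholded at
#'   0.5).
#' @param truth ground-truth [nv_mask].
#' @param spacing mm per voxel (3-vector); taken from `truth` when missing.
#' @return list with `dice_pct`, `ce`, `hd_mm`.
#' @export
evaluate_segmentation <- function(pred, truth, spacing = NULL) {
  pt <- .fg_prob(pred); tt <- .mask_arr(truth)
  if (!identical(dim(pt), dim(tt))) stop("shape mismatch", call. = FALSE)
  if (is.null(spacing))
    spacing <- if (inherits(truth, "nv_volume")) truth$spacing else c(1, 1, 1)
  pb <- pt > 0.5
  if (!any(pb) && !any(tt > 0.5))
    stop("both masks empty: metrics undefined", call. = FALSE)
  dice <- 200 * sum(pb & tt > 0.5) / (sum(pb) + sum(tt > 0.5))
  ce <- ce_loss(pmin(pmax(pt, 1e-7), 1 - 1e-7), tt)
  hd <- .hausdorff_masks(pb, tt > 0.5, spacing)
  list(dice_pct = dice, ce = ce, hd_mm = hd)
}

# surface voxels: mask minus its 6-connected interior
.surface_voxels <- function(m) {
  d <- dim(m)
  if (any(d < 3)) return(m)  # thin grids: everything is surface
  interior <- array(FALSE, d)  # voxels on the grid border are never interior
  interior[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <-
    m[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] &
    m[1:(d[1] - 2), 2:(d[2] - 1), 2:(d[3] - 1)] &
    m[3:d[1], 2:(d[2] - 1), 2:(d[3] - 1)] &
    m[2:(d[1] - 1), 1:(d[2] - 2), 2:(d[3] - 1)] &
    m[2:(d[1] - 1), 3:d[2], 2:(d[3] - 1)] &
    m[2:(d[1] - 1), 2:(d[2] - 1), 1:(d[3] - 2)] &
    m[2:(d[1] - 1), 2:(d[2] - 1), 3:d[3]]
  m & !interior
}

.hausdorff_masks <- function(a, b, spacing) {
  if (!any(a) && !any(b))
    stop("both masks empty: Hausdorff distance undefined", call. = FALSE)
  if (!any(a) || !any(b)) return(Inf)
  sa <- .surface_voxels(a); sb <- .surface_voxels(b)
  da <- cpp_edt3d(sa, dim(a), as.numeric(spacing))
  db <- cpp_edt3d(sb, dim(b), as.numeric(spacing))
  max(max(db[sa]), max(da[sb]))
}

# --- augmentation -----------------------------------------------------------

#' Augmentation parameter ranges
#'
#' Ranges for the five on-the-fly training transforms: random 3D rotation,
#' left-right flip, contrast (gamma), integer translation, and elastic
#' deformation.  Set a range to 0 (or `flip_prob = 0`) to disable a
#' transform.
#'
#' @param rotation_deg max rotation angle (degrees) about a random axis.
#' @param flip_prob probability of a left-right flip.
#' @param contrast_gamma length-2 gamma range.
#' @param translation_vox max translation per axis (voxels, integer).
#' @param elastic_alpha max elastic displacement (voxels).
#' @param elastic_sigma smoothing scale of the displacement field (voxels).
#' @return list of ranges.
#' @export
augment_params <- function(rotation_deg = 15, flip_prob = 0.5,
                           contrast_gamma = c(0.7, 1.5), translation_vox = 10,
                           elastic_alpha = 4, elastic_sigma = 4) {
  list(rotation_deg = rotation_deg, flip_prob = flip_prob,
       contrast_gamma = contrast_gamma, translation_vox = translation_vox,
       elastic_alpha = elastic_alpha, elastic_sigma = elastic_sigma)
}

# smooth a 3D field with three passes of a box blur along each axis
.box_smooth <- function(a, r) {
  if (r < 1) return(a)
  d <- dim(a)
  for (pass in 1:3) for (ax in 1:3) {
    n <- d[ax]
    acc <- a
    cnt <- 1
    for (s in seq_len(min(r, n - 1))) {
      idx_f <- c(seq_len(s), seq_len(n - s))      # clamp at the low edge
      idx_b <- c(seq(s + 1, n), rep(n, s))        # clamp at the high edge
      if (ax == 1) acc <- acc + a[idx_f, , ] + a[idx_b, , ]
      if (ax == 2) acc <- acc + a[, idx_f, ] + a[, idx_b, ]
      if (ax == 3) acc <- acc + a[, , idx_f] + a[, , idx_b]
      cnt <- cnt + 2
    }
    a <- acc / cnt
  }
  a
}

# trilinear / nearest sampling of a 3D array at fractional voxel coordinates
# (1-based); outside the grid returns `fill`
.sample_grid <- function(a, xs, ys, zs, nearest = FALSE, fill = 0) {
  d <- dim(a)
  if (nearest) {
    xi <- round(xs); yi <- round(ys); zi <- round(zs)
    ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
    out <- rep(fill, length(xs))
    out[ok] <- a[cbind(xi[ok], yi[ok], zi[ok])]
    return(out)
  }
  x0 <- floor(xs); y0 <- floor(ys); z0 <- floor(zs)
  fx <- xs - x0; fy <- ys - y0; fz <- zs - z0
  out <- rep(fill, length(xs))
  ok <- x0 >= 1 & x0 + 1 <= d[1] & y0 >= 1 & y0 + 1 <= d[2] &
        z0 >= 1 & z0 + 1 <= d[3]
  if (!any(ok)) return(out)
  x0 <- x0[ok]; y0 <- y0[ok]; z0 <- z0[ok]
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  g <- function(dx, dy, dz) a[cbind(x0 + dx, y0 + dy, z0 + dz)]
  out[ok] <-
    g(0,0,0) * (1-fx)*(1-fy)*(1-fz) + g(1,0,0) * fx*(1-fy)*(1-fz) +
    g(0,1,0) * (1-fx)*fy*(1-fz)     + g(1,1,0) * fx*fy*(1-fz) +
    g(0,0,1) * (1-fx)*(1-fy)*fz     + g(1,0,1) * fx*(1-fy)*fz +
    g(0,1,1) * (1-fx)*fy*fz         + g(1,1,1) * fx*fy*fz
  out
}

# rotation matrix about a unit axis by angle (radians)
.axis_rotation <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Random augmentation of an image/mask pair
#'
#' Applies one random composition of left-right flip, 3D rotation, integer
#' translation, elastic deformation (identical geometric transform for image
#' and mask; trilinear vs. nearest interpolation) and a gamma contrast
#' change (image only).  Deterministic given `seed`.
#'
#' @param image an [nv_volume].
#' @param mask an [nv_mask] aligned with `image`.
#' @param seed integer seed.
#' @param params ranges from [augment_params()].
#' @return list with transformed `image` and `mask`.
#' @export
augment <- function(image, mask, seed, params = augment_params()) {
  stopifnot(inherits(image, "nv_volume"), inherits(mask, "nv_mask"),
            identical(dim(image$data), dim(mask$data)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  d <- dim(image$data)
  do_flip <- stats::runif(1) < params$flip_prob
  ang <- stats::runif(1, -1, 1) * params$rotation_deg * pi / 180
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  tr <- round(stats::runif(3, -1, 1) * params$translation_vox)
  gamma <- stats::runif(1, params$contrast_gamma[1], params$contrast_gamma[2])
  # elastic displacement: smoothed white noise scaled to max norm alpha
  if (params$elastic_alpha > 0) {
    disp <- lapply(1:3, function(i)
      .box_smooth(array(stats::rnorm(prod(d)), d),
                  max(1, round(params$elastic_sigma))))
    nrm <- sqrt(disp[[1]]^2 + disp[[2]]^2 + disp[[3]]^2)
    sc <- params$elastic_alpha / max(nrm, 1e-12)
    disp <- lapply(disp, function(x) x * sc)
  } else disp <- lapply(1:3, function(i) array(0, d))
  R <- .axis_rotation(axis, ang)
  ctr <- (d + 1) / 2
  gx <- rep(seq_len(d[1]), times = d[2] * d[3])
  gy <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  gz <- rep(seq_len(d[3]), each = d[1] * d[2])
  # inverse map: source = R^-1 (target - ctr - t) + ctr - elastic
  P <- rbind(gx - ctr[1] - tr[1], gy - ctr[2] - tr[2], gz - ctr[3] - tr[3])
  S <- t(R) %*% P
  sx <- S[1, ] + ctr[1] - as.vector(disp[[1]])
  sy <- S[2, ] + ctr[2] - as.vector(disp[[2]])
  sz <- S[3, ] + ctr[3] - as.vector(disp[[3]])
  if (do_flip) sx <- d[1] + 1 - sx
  img <- array(.sample_grid(image$data, sx, sy, sz, fill = min(image$data)), d)
  msk <- array(.sample_grid(mask$data * 1.0, sx, sy, sz, nearest = TRUE,
                            fill = 0) > 0.5, d)
  img <- minmax_normalize(nv_volume(img, image$spacing, image$origin))
  img$data <- img$data^gamma
  list(image = img, mask = nv_mask(msk, mask$spacing, mask$origin))
}

# --- training ---------------------------------------------------------------

#' Training configuration
#'
#' Adam with the usual moment parameters; L2 weight decay added to the
#' gradient; loss is a weighted Dice + cross-entropy combination.
#'
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam moment decay rates.
#' @param weight_decay L2 coefficient.
#' @param epochs training epochs.
#' @param batch_size samples per step (gradients averaged).
#' @param loss `"dice+ce"`, `"dice"` or `"ce"`.
#' @param loss_weights length-2 `(dice, ce)` weights used when
#'   `loss = "dice+ce"`.
#' @param folds cross-validation folds (used by [cross_validate]).
#' @param seed RNG seed for shuffling/augmentation.
#' @param augment apply on-the-fly augmentation during training.
#' @param augment_params ranges from [augment_params()].
#' @return `nv_trainconfig` list.
#' @export
train_config <- function(learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.99,
                         weight_decay = 0.01, epochs = 100, batch_size = 1,
                         loss = c("dice+ce", "dice", "ce"),
                         loss_weights = c(1, 1), folds = 5, seed = 1,
                         augment = FALSE, augment_params = NULL) {
  loss <- match.arg(loss)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (beta1 <= 0 || beta1 >= 1 || beta2 <= 0 || beta2 >= 1)
    stop("beta1, beta2 must lie in (0, 1)", call. = FALSE)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (any(loss_weights < 0) || sum(loss_weights) == 0)
    stop("loss_weights must be non-negative, not both zero", call. = FALSE)
  w <- switch(loss, "dice+ce" = loss_weights, dice = c(1, 0), ce = c(0, 1))
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), loss = loss,
                 loss_weights = w, folds = as.integer(folds),
                 seed = as.integer(seed), augment = augment,
                 augment_params = augment_params %||% augment_params()),
            class = "nv_trainconfig")
}

#' Train a segmentation model on (volume, mask) patches
#'
#' Plain Adam optimization of the configured loss over the patch dataset,
#' seeded and reproducible.  Diverging (NaN) loss raises an error naming the
#' epoch.
#'
#' @param model an `nv_model` from [build_model].
#' @param dataset list of `list(image = nv_volume|array, mask = nv_mask|array)`
#'   patches matching the model patch shape.
#' @param cfg an [train_config].
#' @return list with the trained `model` and a tibble `history`
#'   (epoch, loss).
#' @export
train_model <- function(model, dataset, cfg) {
  stopifnot(inherits(model, "nv_model"), inherits(cfg, "nv_trainconfig"))
  if (length(dataset) == 0) stop("empty dataset", call. = FALSE)
  if (cfg$epochs == 0)
    return(list(model = model, history = tibble::tibble(epoch = integer(0),
                                                        loss = numeric(0))))
  P <- model$params
  mstate <- lapply(P, function(p) array(0, dim(p) %||% length(p)))
  vstate <- mstate
  t_step <- 0
  hist <- numeric(cfg$epochs)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(cfg$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  arr_of <- function(x) if (inherits(x, "nv_volume")) x$data else x
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(length(dataset))
    losses <- numeric(0)
    for (batch in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      gacc <- NULL
      bl <- 0
      for (si in batch) {
        smp <- dataset[[si]]
        if (cfg$augment) {
          aug <- augment(as_nv_volume(smp$image), as_nv_mask(smp$mask),
                         seed = stats::runif(1, 1, 2^30),
                         params = cfg$augment_params)
          img <- aug$image$data; msk <- aug$mask$data * 1.0
        } else {
          img <- arr_of(smp$image); msk <- .mask_arr(smp$mask)
        }
        model$params <- P
        fw <- model_forward(model, img, keep_cache = TRUE)
        l <- combined_loss(fw$probs, msk, cfg$loss_weights)
        if (!is.finite(l))
          stop(sprintf("divergence: non-finite loss at epoch %d", ep),
               call. = FALSE)
        bl <- bl + l
        dlog <- .loss_grad_logits(fw$probs, msk, cfg$loss_weights)
        gr <- model_backward(model, fw$cache, dlog)
        if (is.null(gacc)) gacc <- gr
        else for (nm in names(gr)) gacc[[nm]] <- gacc[[nm]] + gr[[nm]]
      }
      nb <- length(batch)
      t_step <- t_step + 1
      for (nm in names(P)) {
        g <- gacc[[nm]] / nb + cfg$weight_decay * P[[nm]]
        mstate[[nm]] <- cfg$beta1 * mstate[[nm]] + (1 - cfg$beta1) * g
        vstate[[nm]] <- cfg$beta2 * vstate[[nm]] + (1 - cfg$beta2) * g^2
        mhat <- mstate[[nm]] / (1 - cfg$beta1^t_step)
        vhat <- vstate[[nm]] / (1 - cfg$beta2^t_step)
        P[[nm]] <- P[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + 1e-8)
      }
      losses <- c(losses, bl / nb)
    }
    hist[ep] <- mean(losses)
  }
  model$params <- P
  list(model = model,
       history = tibble::tibble(epoch = seq_len(cfg$epochs), loss = hist))
}

as_nv_volume <- function(x, spacing = c(1, 1, 1)) {
  if (inherits(x, "nv_volume")) x else nv_volume(x, spacing)
}
as_nv_mask <- function(x, spacing = c(1, 1, 1)) {
  if (inherits(x, "nv_mask")) x
  else if (inherits(x, "nv_volume")) nv_mask(x$data > 0.5, x$spacing, x$origin)
  else nv_mask(x, spacing)
}

#' Patient-wise k-fold cross-validation
#'
#' Folds partition patients, never patches, so both joints (and all patches)
#' of a patient always share a fold and no validation patient leaks into
#' training.
#'
#' @param cohort list of patients; each patient is a list with `id` and
#'   `samples` (a list of `list(image, mask)` patches).
#' @param model_cfg a [network_config] used to build each fold's model.
#' @param cfg an [train_config]; `cfg$folds` folds are used.
#' @return list with `folds` (tibble patient/fold assignment), `metrics`
#'   (per-sample tibble) and `summary` (mean/sd per metric, the layout of a
#'   per-architecture results table).
#' @export
cross_validate <- function(cohort, model_cfg, cfg) {
  n <- length(cohort)
  if (n < cfg$folds)
    stop("fewer patients than folds", call. = FALSE)
  ids <- vapply(cohort, function(p) as.character(p$id), character(1))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(cfg$seed)
  fold_of <- sample(rep(seq_len(cfg$folds), length.out = n))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  rows <- list()
  for (f in seq_len(cfg$folds)) {
    tr_idx <- which(fold_of != f); va_idx <- which(fold_of == f)
    train_set <- unlist(lapply(cohort[tr_idx], `[[`, "samples"),
                        recursive = FALSE)
    model <- build_model(model_cfg, seed = cfg$seed + f)
    fit <- train_model(model, train_set, cfg)
    for (vi in va_idx) {
      for (s in cohort[[vi]]$samples) {
        p <- predict_volume(fit$model, as_nv_volume(s$image))
        truth <- as_nv_mask(s$mask)
        m <- evaluate_segmentation(p, truth)
        rows[[length(rows) + 1]] <- tibble::tibble(
          patient = cohort[[vi]]$id, fold = f, dice_pct = m$dice_pct,
          ce = m$ce, hd_mm = m$hd_mm)
      }
    }
  }
  metrics <- do.call(rbind, rows)
  summary <- tibble::tibble(
    architecture = model_cfg$architecture,
    score = c("dice_pct", "ce", "hd_mm"),
    mean = c(mean(metrics$dice_pct), mean(metrics$ce), mean(metrics$hd_mm)),
    sd = c(stats::sd(metrics$dice_pct), stats::sd(metrics$ce),
           stats::sd(metrics$hd_mm)))
  list(folds = tibble::tibble(patient = ids, fold = fold_of),
       metrics = metrics, summary = summary)
}
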