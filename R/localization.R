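# Coarse joint localization: low-resolution segmentation, minimum-method
# thresholding with outlier removal, and left/right VOI bounding boxes.

#' Minimum-method histogram threshold
#'
#' The histogram (default 256 bins) is repeatedly smoothed with a 3-bin
#' moving average until exactly two local maxima remain (the classical
#' Prewitt-Mendelsohn iteration); the threshold is the deepest valley
#' between them.  If smoothing collapses to a single maximum first, the
#' histogram is unimodal and no valley exists.
#'
#' @param x numeric values.
#' @param bins number of histogram bins.
#' @param max_iter smoothing iteration cap.
#' @return list with `threshold` (bin-centre value, `NA` if unimodal),
#'   `unimodal` flag, `iterations`, and the smoothed `counts`.
#' @export
threshold_minimum <- function(x, bins = 256, max_iter = 10000) {
  x <- x[is.finite(x)]
  lo <- min(x); hi <- max(x)
  if (hi <= lo)
    return(list(threshold = NA_real_, unimodal = TRUE, iterations = 0L,
                counts = rep(length(x), 1)))
  h <- hist(x, breaks = seq(lo, hi, length.out = bins + 1), plot = FALSE)
  counts <- as.numeric(h$counts)
  centers <- h$mids
  n_modes <- function(cn) {
    # strict local maxima of the padded sequence, plateaus counted once
    r <- rle(cn)
    v <- r$values
    if (length(v) == 1) return(1L)
    left <- c(-Inf, v[-length(v)]); right <- c(v[-1], -Inf)
    sum(v > left & v > right)
  }
  it <- 0L
  while (n_modes(counts) > 2 && it < max_iter) {
    counts <- (c(counts[1], counts[-length(counts)]) + counts +
               c(counts[-1], counts[length(counts)])) / 3
    it <- it + 1L
  }
  if (n_modes(counts) < 2)
    return(list(threshold = NA_real_, unimodal = TRUE, iterations = it,
                counts = counts))
  # keep smoothing until two modes (if we started with > 2 and capped out)
  if (n_modes(counts) > 2)
    return(list(threshold = NA_real_, unimodal = TRUE, iterations = it,
                counts = counts))
  # locate the two maxima and the deepest valley between them
  r <- rle(counts)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  v <- r$values
  left <- c(-Inf, v[-length(v)]); right <- c(v[-1], -Inf)
  peaks <- which(v > left & v > right)
  p1 <- ends[peaks[1]]; p2 <- starts[peaks[2]]
  between <- p1:p2
  valley <- between[which.min(counts[between])]
  # separation = smaller peak over valley depth; >> 1 for well-separated
  # modes, ~1 for spurious splits of a single noisy mode
  list(threshold = centers[valley], unimodal = FALSE, iterations = it,
       counts = counts,
       mode_separation = min(v[peaks]) / max(counts[valley],
                                             .Machine$double.eps))
}

#' Coarse joint-probability segmentation at localization resolution
#'
#' Runs a segmentation model on a (typically downsampled) volume and returns
#' the per-voxel foreground probability.
#'
#' @param v an [nv_volume], already resampled to the localization
#'   resolution the model was trained at.
#' @param model a model from [build_model] (trained via [train_model]).
#' @return An [nv_volume] of probabilities in \[0, 1\].
#' @export
coarse_segment <- function(v, model) {
  stopifnot(inherits(v, "nv_volume"))
  p <- predict_volume(model, v)
  nv_volume(p, v$spacing, v$origin)
}

#' Postprocess a probability field into a localization mask
#'
#' Thresholds with the minimum method on the probability histogram, then
#' opens the mask and removes connected components much smaller than the
#' largest.  A unimodal histogram falls back to a fixed 0.5 threshold with a
#' warning.
#'
#' @param p probability [nv_volume] in \[0, 1\].
#' @param open_radius opening radius (voxels).
#' @param min_fraction small-component removal fraction.
#' @return An [nv_mask].
#' @export
postprocess_localization <- function(p, open_radius = 1, min_fraction = 0.1) {
  stopifnot(inherits(p, "nv_volume"))
  if (min(p$data) < -1e-9 || max(p$data) > 1 + 1e-9)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  tm <- threshold_minimum(as.vector(p$data))
  if (tm$unimodal) {
    warning("unimodal probability histogram; falling back to threshold 0.5")
    thr <- 0.5
  } else thr <- tm$threshold
  m <- nv_mask(p$data > thr, p$spacing, p$origin)
  if (!any(m$data)) {
    warning("empty localization mask")
    return(m)
  }
  m <- open_mask(m, open_radius)
  if (any(m$data)) m <- drop_small_components(m, min_fraction)
  m
}

#' Axis-aligned VOI bounding box
#'
#' Half-open voxel index box `[min_index, max_index)` (1-based min, so a box
#' covering voxel 1 alone is `min_index = 1`, `max_index = 2`).
#'
#' @param min_index,max_index integer length-3.
#' @param side `"left"` or `"right"`.
#' @return `nv_bbox` object.
#' @export
bounding_box <- function(min_index, max_index, side = c("left", "right")) {
  side <- match.arg(side)
  min_index <- as.integer(min_index); max_index <- as.integer(max_index)
  if (any(min_index >= max_index)) stop("degenerate bounding box", call. = FALSE)
  structure(list(min_index = min_index, max_index = max_index, side = side),
            class = "nv_bbox")
}

#' @export
print.nv_bbox <- function(x, ...) {
  cat(sprintf("<nv_bbox %s> [%s) x [%s) x [%s)\n", x$side,
              paste(x$min_index[1], x$max_index[1], sep = ", "),
              paste(x$min_index[2], x$max_index[2], sep = ", "),
              paste(x$min_index[3], x$max_index[3], sep = ", ")))
  invisible(x)
}

# tight box of a logical array, 1-based half-open
.tight_box <- function(dat) {
  idx <- which(dat, arr.ind = TRUE)
  list(min = apply(idx, 2, min), max = apply(idx, 2, max) + 1L)
}

#' Extract left and right VOI boxes from a localization mask
#'
#' Takes the two largest connected components, pads their tight boxes by a
#' margin, labels them left/right by centroid x-coordinate relative to the
#' volume midline (left = smaller x), and optionally rescales indices to a
#' full-resolution grid.
#'
#' @param m localization [nv_mask].
#' @param margin fractional padding per axis (default 10%).
#' @param full_shape optional integer length-3: rescale indices to this
#'   full-resolution grid shape.
#' @return list with elements `left` and `right` ([bounding_box] objects).
#' @export
extract_voi_boxes <- function(m, margin = 0.1, full_shape = NULL) {
  stopifnot(inherits(m, "nv_mask"))
  lab <- label_components(m)
  n <- attr(lab, "n")
  if (n < 2) stop("localization failure: fewer than 2 components", call. = FALSE)
  d <- dim(m$data)
  mid <- (d[1] + 1) / 2
  cx <- vapply(seq_len(n), function(l) mean(which(lab == l, arr.ind = TRUE)[, 1]),
               numeric(1))
  left_ids <- which(cx < mid); right_ids <- which(cx >= mid)
  if (length(left_ids) == 0 || length(right_ids) == 0)
    stop("localization failure: all components on one body side", call. = FALSE)
  boxes <- list(.tight_box(array(lab %in% left_ids, d)),
                .tight_box(array(lab %in% right_ids, d)))
  cents <- list(colMeans(which(array(lab %in% left_ids, d), arr.ind = TRUE)),
                colMeans(which(array(lab %in% right_ids, d), arr.ind = TRUE)))
  out <- list()
  for (i in 1:2) {
    b <- boxes[[i]]
    pad <- pmax(1L, as.integer(ceiling((b$max - b$min) * margin)))
    mn <- pmax(b$min - pad, 1L)
    mx <- pmin(b$max + pad, d + 1L)
    if (!is.null(full_shape)) {
      sc <- full_shape / d
      mn <- pmax(1L, as.integer(floor((mn - 1L) * sc)) + 1L)
      mx <- pmin(as.integer(ceiling((mx - 1L) * sc)) + 1L, as.integer(full_shape) + 1L)
    }
    bb <- bounding_box(mn, mx, side = c("left", "right")[i])
    # mass centroid of the side's components (full-resolution voxel coords);
    # more robust than the box centre when thin structures are missed
    cent <- cents[[i]]
    if (!is.null(full_shape)) cent <- (cent - 0.5) * (full_shape / d) + 0.5
    bb$centroid <- cent
    out[[c("left", "right")[i]]] <- bb
  }
  out
}

#' Fixed-shape box centred on a point
#'
#' Builds a `shape`-sized half-open voxel box centred on `centroid_vox`,
#' shifted as needed to fit the grid.
#'
#' @param centroid_vox length-3 voxel coordinates (1-based, fractional ok).
#' @param shape integer length-3 box size.
#' @param grid_dim grid dimensions.
#' @param side box label.
#' @return An [bounding_box].
#' @export
centered_box <- function(centroid_vox, shape, grid_dim,
                         side = c("left", "right")) {
  shape <- as.integer(shape)
  mn <- as.integer(round(centroid_vox - shape / 2)) + 1L
  mn <- pmin(pmax(mn, 1L), as.integer(grid_dim) - shape + 1L)
  bounding_box(mn, mn + shape, side = match.arg(side))
}

#' Crop a volume to a bounding box
#'
#' Optionally centre-pads / centre-crops the result to a fixed patch shape
#' (padding with the volume minimum).
#'
#' @param v an [nv_volume] or [nv_mask].
#' @param b an [bounding_box].
#' @param patch_shape optional fixed output shape.
#' @return Cropped object of the same class, origin shifted accordingly.
#' @export
crop_voi <- function(v, b, patch_shape = NULL) {
  stopifnot(inherits(v, "nv_volume"), inherits(b, "nv_bbox"))
  d <- dim(v$data)
  if (any(b$min_index < 1L) || any(b$max_index > d + 1L))
    stop("bounding box out of volume bounds", call. = FALSE)
  dat <- v$data[b$min_index[1]:(b$max_index[1] - 1L),
                b$min_index[2]:(b$max_index[2] - 1L),
                b$min_index[3]:(b$max_index[3] - 1L), drop = FALSE]
  org <- v$origin + (b$min_index - 1L) * v$spacing
  if (!is.null(patch_shape)) {
    patch_shape <- as.integer(patch_shape)
    fill <- if (is.logical(dat)) FALSE else min(dat)
    out <- array(fill, patch_shape)
    src <- dim(dat)
    # centre alignment; crop when larger, pad when smaller
    off_src <- pmax((src - patch_shape) %/% 2L, 0L)
    off_dst <- pmax((patch_shape - src) %/% 2L, 0L)
    len <- pmin(src, patch_shape)
    out[off_dst[1] + 1:len[1], off_dst[2] + 1:len[2], off_dst[3] + 1:len[3]] <-
      dat[off_src[1] + 1:len[1], off_src[2] + 1:len[2], off_src[3] + 1:len[3]]
    dat <- out
    org <- org + (off_src - off_dst) * v$spacing
  }
  if (inherits(v, "nv_mask")) nv_mask(dat, v$spacing, org)
  else nv_volume(dat, v$spacing, org)
}

# paste a cropped volume back into a host grid (for round-trip checks and
# re-embedding VOI segmentations)
embed_voi <- function(host, cropped, b) {
  dat <- host$data
  dat[b$min_index[1]:(b$max_index[1] - 1L),
      b$min_index[2]:(b$max_index[2] - 1L),
      b$min_index[3]:(b$max_index[3] - 1L)] <- cropped$data
  if (inherits(host, "nv_mask")) nv_mask(dat, host$spacing, host$origin)
  else nv_volume(dat, host$spacing, host$origin)
}
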