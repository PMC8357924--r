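# Classical image-processing route for the socket (temporal) bone: median
# denoising, minimum-method bone thresholding, morphological edge closing
# and smoothing, slice-wise Canny edges linked across slices, and boundary
# filling; plus fusion with a network heatmap and the slice-stack smoothing
# that precedes 3D reconstruction.

#' Classical socket-bone mask (enhancement route)
#'
#' Ordered stages: median denoise -> minimum-method intensity threshold to
#' candidate bone -> morphological closing (edge closing) -> erosion/dilation
#' smoothing (opening) -> slice-wise Canny edges linked across slices, used
#' to close remaining boundary gaps near the mask -> hole filling.  Volumes
#' without bone structure are rejected: if the histogram is unimodal, or if
#' the thresholded candidate mask is mere speckle (fewer than `min_solidity`
#' of its voxels survive an opening), an empty mask is returned with a
#' warning.
#'
#' @param v an [nv_volume] normalized to \[0, 1\].
#' @param median_radius slice-wise median window radius (voxels).
#' @param close_radius,smooth_radius closing / opening radii (voxels).
#' @param canny_low,canny_high Canny hysteresis quantiles.
#' @param edge_mode see [canny_edges].
#' @param min_solidity minimum fraction of thresholded voxels surviving an
#'   opening; random speckle from a spurious threshold on unstructured noise
#'   has near-zero solidity, solid bone is largely preserved.
#' @param min_minority_fraction minimum voxel fraction of the smaller side of
#'   the threshold; a spurious valley in a distribution tail leaves almost
#'   no mass on one side, a true bone/background split never does.
#' @return An [nv_mask].
#' @export
classical_tb_mask <- function(v, median_radius = 1, close_radius = 1,
                              smooth_radius = 1, canny_low = 0.6,
                              canny_high = 0.85,
                              edge_mode = "canny2d-linked",
                              min_solidity = 0.2,
                              min_minority_fraction = 0.02) {
  stopifnot(inherits(v, "nv_volume"))
  if (min(v$data) < -1e-9 || max(v$data) > 1 + 1e-9)
    stop("input must be normalized to [0, 1]", call. = FALSE)
  empty <- function() nv_mask(array(FALSE, dim(v$data)), v$spacing, v$origin)
  if (max(v$data) - min(v$data) < 1e-12) {
    warning("flat input volume: empty bone mask")
    return(empty())
  }
  den <- nv_volume(cpp_median2d_stack(v$data, dim(v$data),
                                      as.integer(median_radius)),
                   v$spacing, v$origin)
  tm <- threshold_minimum(as.vector(den$data))
  if (tm$unimodal) {
    warning("unimodal intensity histogram (no bone mode): empty mask")
    return(empty())
  }
  m <- nv_mask(den$data > tm$threshold, v$spacing, v$origin)
  frac <- mean(m$data)
  if (min(frac, 1 - frac) < min_minority_fraction) {
    warning("spurious tail threshold (no bone mode of meaningful size): empty mask")
    return(empty())
  }
  opened <- open_mask(m, max(1, smooth_radius))
  if (sum(opened$data) / sum(m$data) < min_solidity) {
    warning("thresholded mask is unstructured speckle: empty mask")
    return(empty())
  }
  m <- close_mask(m, close_radius)
  m <- open_mask(m, smooth_radius)
  if (!any(m$data)) {
    warning("bone mask empty after morphology")
    return(m)
  }
  edges <- canny_edges(den, low = canny_low, high = canny_high, mode = edge_mode)
  near <- dilate_mask(m, 2)
  m2 <- nv_mask(m$data | (edges$data & near$data), v$spacing, v$origin)
  fill_holes(m2)
}

#' Fuse a classical mask with a network heatmap
#'
#' The fused mask is the classical mask restricted to the dilated region
#' where the heatmap is at least `tau`, united with the heatmap's own
#' high-confidence core (`heatmap >= tau_core`).  Guarantees
#' `core ⊆ output ⊆ classical ∪ core`, and raising `tau` never grows the
#' output.
#'
#' @param classical an [nv_mask].
#' @param heatmap probability [nv_volume], same grid.
#' @param tau support threshold in (0, 1).
#' @param tau_core core threshold (>= tau).
#' @param dilate_radius dilation of the heatmap support region (voxels).
#' @return An [nv_mask].
#' @export
fuse_with_heatmap <- function(classical, heatmap, tau = 0.5, tau_core = 0.9,
                              dilate_radius = 3) {
  stopifnot(inherits(classical, "nv_mask"), inherits(heatmap, "nv_volume"),
            identical(dim(classical$data), dim(heatmap$data)))
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)", call. = FALSE)
  sup <- nv_mask(heatmap$data >= tau, heatmap$spacing, heatmap$origin)
  if (any(sup$data)) sup <- dilate_mask(sup, dilate_radius)
  core <- heatmap$data >= tau_core
  nv_mask((classical$data & sup$data) | core, classical$spacing,
          classical$origin)
}

#' Slice-stack smoothing before 3D reconstruction
#'
#' Slice-wise 2D median filtering with a radius matched to the irregularity
#' scale, followed by linear interpolation of the (soft) mask along z to the
#' reconstruction pitch.  Output is ready for [mask_to_mesh].
#'
#' @param m an [nv_mask].
#' @param radius median filter radius (voxels), matched to the size of the
#'   irregularities to remove.
#' @param target_pitch optional z pitch (mm) to interpolate the stack to
#'   (default: keep the input pitch).
#' @return An [nv_mask].
#' @export
smooth_stack <- function(m, radius = 1, target_pitch = NULL) {
  stopifnot(inherits(m, "nv_mask"))
  if (!any(m$data)) stop("empty mask", call. = FALSE)
  d <- dim(m$data)
  if (2 * radius + 1 > min(d[1], d[2]))
    stop("median radius larger than slice", call. = FALSE)
  soft <- cpp_median2d_stack(m$data * 1.0, d, as.integer(radius))
  sp <- m$spacing
  if (!is.null(target_pitch) && abs(target_pitch - sp[3]) > 1e-9) {
    nz <- max(2L, as.integer(round(d[3] * sp[3] / target_pitch)))
    vol <- resample(nv_volume(soft, sp, m$origin), c(d[1], d[2], nz))
    soft <- vol$data; sp <- vol$spacing
    return(nv_mask(soft >= 0.5, sp, vol$origin))
  }
  nv_mask(soft >= 0.5, sp, m$origin)
}
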