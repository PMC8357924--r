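# Left-right symmetry of negative volumes: Hausdorff cloud-to-cloud distance
#   H_LR = max{ sup_l inf_r d(l, r), sup_r inf_l d(l, r) }
# and the surface-area ratio
#   S_LR = max{S_L, S_R} / min{S_L, S_R},
# computed after mirroring the right mesh across the mid-sagittal plane and
# (optionally) rigidly refining the alignment.

#' Hausdorff distance between two point clouds
#'
#' The maximum over both directions of the sup-inf Euclidean point-set
#' distance, in the units of the coordinates (mm throughout this package).
#'
#' @param l,r N x 3 numeric matrices (or objects with `$vertices`).
#' @return numeric scalar >= 0.
#' @export
hausdorff_distance <- function(l, r) {
  pts <- function(x) {
    if (inherits(x, "nv_mesh")) x <- x$vertices
    x <- as.matrix(x)
    if (nrow(x) == 0) stop("empty point cloud", call. = FALSE)
    if (ncol(x) != 3 || any(!is.finite(x)))
      stop("point clouds must be finite N x 3 matrices", call. = FALSE)
    x
  }
  A <- pts(l); B <- pts(r)
  max(cpp_hausdorff_directed(A, B), cpp_hausdorff_directed(B, A))
}

#' Surface-area ratio of the two sides
#'
#' `max(sl, sr) / min(sl, sr)`; always >= 1 and symmetric in its arguments.
#'
#' @param sl,sr surface areas (mm^2), > 0.
#' @return numeric >= 1.
#' @export
surface_ratio <- function(sl, sr) {
  if (!is.finite(sl) || !is.finite(sr) || sl <= 0 || sr <= 0)
    stop("areas must be positive", call. = FALSE)
  max(sl, sr) / min(sl, sr)
}

#' Mirror a mesh across the mid-sagittal plane, optionally refining
#'
#' Reflects across the given plane (winding is reversed so orientation stays
#' outward).  With `refine = "centroid"` the mirrored mesh is translated so
#' the centroids coincide with `target`'s; `refine = "icp"` additionally
#' runs a rigid iterative-closest-point alignment.  The applied transform is
#' attached as attribute `"alignment"`.
#'
#' @param right the right-side [nv_mesh].
#' @param mid_plane list with `point` and `normal`.
#' @param refine `"none"`, `"centroid"` or `"icp"`.
#' @param target left-side mesh for refinement (required unless "none").
#' @param icp_iters ICP iterations.
#' @return Mirrored (aligned) [nv_mesh].
#' @export
mirror_align <- function(right, mid_plane, refine = c("none", "centroid", "icp"),
                         target = NULL, icp_iters = 15) {
  stopifnot(inherits(right, "nv_mesh"))
  refine <- match.arg(refine)
  if (nrow(right$vertices) < 3) stop("degenerate mesh", call. = FALSE)
  n <- mid_plane$normal / sqrt(sum(mid_plane$normal^2))
  R <- diag(3) - 2 * tcrossprod(n)
  t0 <- 2 * sum(mid_plane$point * n) * n
  out <- transform_mesh(right, R, t0)
  align <- list(reflection = R, translation = t0, refine = refine)
  if (refine != "none") {
    if (is.null(target)) stop("refinement needs a target mesh", call. = FALSE)
    shift <- colMeans(target$vertices) - colMeans(out$vertices)
    out <- transform_mesh(out, diag(3), shift)
    align$centroid_shift <- shift
    if (refine == "icp") {
      for (i in seq_len(icp_iters)) {
        idx <- cpp_nn_index(out$vertices, target$vertices)
        Q <- target$vertices[idx, , drop = FALSE]
        mu_p <- colMeans(out$vertices); mu_q <- colMeans(Q)
        H <- crossprod(sweep(out$vertices, 2, mu_p),
                       sweep(Q, 2, mu_q))
        sv <- svd(H)
        Ri <- sv$v %*% t(sv$u)
        if (det(Ri) < 0) { sv$v[, 3] <- -sv$v[, 3]; Ri <- sv$v %*% t(sv$u) }
        ti <- mu_q - as.vector(Ri %*% mu_p)
        out <- transform_mesh(out, Ri, ti)
      }
      align$icp_iters <- icp_iters
    }
  }
  attr(out, "alignment") <- align
  out
}

#' Left-right symmetry report of two negative volumes
#'
#' Mirrors the right mesh across the mid-sagittal plane, aligns it, samples
#' point clouds from both surfaces, and computes `H_LR` (with a subsampling
#' spread: mean and sd over seeded 50% subsamples) plus `S_LR`, per-side
#' surface areas and volumes.  A pair is flagged asymmetric when `S_LR`
#' exceeds `s_lr_flag`.
#'
#' @param left,right watertight negative-volume [nv_mesh]es.
#' @param mid_plane mid-sagittal plane (`point`, `normal`); default the
#'   yz-plane through x = 0 is rarely right, so pass the scan's midline.
#' @param refine alignment refinement, see [mirror_align].
#' @param sampling `"vertices"` (default) or `"surface"` (uniform-area
#'   sampling of `n_points` points).
#' @param n_points surface sample size.
#' @param n_subsamples,subsample_frac resampling scheme behind the H_LR
#'   spread.
#' @param s_lr_flag asymmetry flag threshold on S_LR (heuristic, not
#'   clinical guidance).
#' @param seed RNG seed for sampling.
#' @return `nv_symmetry_report` list; see fields in the description.
#' @export
symmetry_report <- function(left, right,
                            mid_plane = list(point = c(0, 0, 0),
                                             normal = c(1, 0, 0)),
                            refine = "centroid",
                            sampling = c("vertices", "surface"),
                            n_points = 1e4, n_subsamples = 20,
                            subsample_frac = 0.5, s_lr_flag = 1.15,
                            seed = 1) {
  stopifnot(inherits(left, "nv_mesh"), inherits(right, "nv_mesh"))
  sampling <- match.arg(sampling)
  ml <- mesh_measures(left); mr <- mesh_measures(right)
  rmir <- mirror_align(right, mid_plane, refine = refine, target = left)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  cl <- if (sampling == "vertices") left$vertices
        else sample_surface(left, n_points)
  cr <- if (sampling == "vertices") rmir$vertices
        else sample_surface(rmir, n_points)
  h <- hausdorff_distance(cl, cr)
  hs <- vapply(seq_len(n_subsamples), function(i) {
    il <- sample(nrow(cl), max(2, round(subsample_frac * nrow(cl))))
    ir <- sample(nrow(cr), max(2, round(subsample_frac * nrow(cr))))
    hausdorff_distance(cl[il, , drop = FALSE], cr[ir, , drop = FALSE])
  }, numeric(1))
  s_lr <- surface_ratio(ml$area, mr$area)
  structure(list(
    H_LR = h, H_LR_mean = mean(hs), H_LR_sd = stats::sd(hs),
    S_LR = s_lr, S_L = ml$area, S_R = mr$area,
    V_L = ml$volume, V_R = mr$volume,
    asymmetric = s_lr > s_lr_flag, s_lr_flag = s_lr_flag,
    alignment = attr(rmir, "alignment"),
    sampling = sampling, n_subsamples = n_subsamples,
    subsample_frac = subsample_frac, seed = seed), class = "nv_symmetry_report")
}

#' @export
print.nv_symmetry_report <- function(x, ...) {
  cat(sprintf("<symmetry report>  S_LR = %.3f   H_LR = %.3f mm (subsampled %.2f +/- %.2f)\n",
              x$S_LR, x$H_LR, x$H_LR_mean, x$H_LR_sd))
  cat(sprintf("  S_L %.1f mm^2, S_R %.1f mm^2; V_L %.1f mm^3, V_R %.1f mm^3\n",
              x$S_L, x$S_R, x$V_L, x$V_R))
  cat(sprintf("  asymmetric (S_LR > %.2f): %s\n", x$s_lr_flag, x$asymmetric))
  invisible(x)
}

#' One-row tibble form of a symmetry report
#'
#' @param x an `nv_symmetry_report`.
#' @return A 1-row tibble mirroring the per-patient results-table layout.
#' @export
symmetry_report_row <- function(x) {
  stopifnot(inherits(x, "nv_symmetry_report"))
  tibble::tibble(S_LR = x$S_LR, H_LR = x$H_LR, H_LR_mean = x$H_LR_mean,
                 H_LR_sd = x$H_LR_sd, S_L = x$S_L, S_R = x$S_R,
                 V_L = x$V_L, V_R = x$V_R, asymmetric = x$asymmetric)
}

#' Serialize a symmetry report to JSON
#'
#' @param x an `nv_symmetry_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_symmetry_report <- function(x, path) {
  stopifnot(inherits(x, "nv_symmetry_report"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Uniform-area point sampling on a mesh surface
#'
#' @param m an [nv_mesh].
#' @param n number of points.
#' @return n x 3 matrix of points on the surface.
#' @export
sample_surface <- function(m, n) {
  fn <- face_normals_raw(m)
  areas <- sqrt(rowSums(fn^2)) / 2
  fi <- sample.int(nrow(m$faces), n, replace = TRUE, prob = areas)
  r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
  a <- m$vertices[m$faces[fi, 1], , drop = FALSE]
  b <- m$vertices[m$faces[fi, 2], , drop = FALSE]
  cc <- m$vertices[m$faces[fi, 3], , drop = FALSE]
  (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * cc
}
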