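#' 3D scalar volume with physical geometry
#'
#' A volume is a 3D intensity grid plus its voxel geometry: `spacing` gives
#' the mm extent of a voxel along each axis and `origin` the mm position of
#' the centre of voxel (1,1,1).  Axial slices run along the third (z) axis.
#' Voxel `(i,j,k)` (1-based) occupies the half-open cube
#' `[origin + (i-1)*spacing, origin + i*spacing)` and its centre is at
#' `origin + (i-1)*spacing`.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing numeric length-3, mm per voxel along (x, y, z); all > 0.
#' @param origin numeric length-3, mm coordinates of the first voxel centre.
#' @return An object of class `nv_volume`.
#' @export
nv_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "nv_volume")
}

#' Binary occupancy mask aligned to a volume grid
#'
#' @param data 3D array coercible to 0/1 (logical or numeric).
#' @inheritParams nv_volume
#' @return An object of class `nv_mask` (also an `nv_volume`).
#' @export
nv_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("mask data must be a 3D array", call. = FALSE)
  d <- dim(data)
  data <- array(as.logical(data), d)
  if (anyNA(data)) stop("mask values must be 0/1", call. = FALSE)
  v <- nv_volume(array(0, c(1, 1, 1)), spacing, origin)
  structure(list(data = data, spacing = v$spacing, origin = v$origin),
            class = c("nv_mask", "nv_volume"))
}

#' @export
print.nv_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  if (inherits(x, "nv_mask")) {
    cat(sprintf("  foreground: %d voxels (%.2f%%)\n", sum(x$data),
                100 * mean(x$data)))
  } else {
    cat(sprintf("  intensity range: [%.4g, %.4g]\n",
                min(x$data), max(x$data)))
  }
  invisible(x)
}

#' @export
dim.nv_volume <- function(x) dim(x$data)

# same grid geometry (shape, spacing, origin)?
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Min-max intensity normalization
#'
#' Maps intensities linearly onto \[0, 1\]:
#' `(x - min) / (max - min)`.  A constant volume maps to all zeros, which
#' keeps the operation well defined without dividing by zero.  The operation
#' is idempotent.
#'
#' @param v an [nv_volume].
#' @return An `nv_volume` with intensities in \[0, 1\].
#' @export
minmax_normalize <- function(v) {
  stopifnot(inherits(v, "nv_volume"))
  if (any(!is.finite(v$data))) stop("non-finite intensities", call. = FALSE)
  lo <- min(v$data); hi <- max(v$data)
  out <- if (hi > lo) (v$data - lo) / (hi - lo) else array(0, dim(v$data))
  nv_volume(out, v$spacing, v$origin)
}

#' Physical extent of a volume in mm
#'
#' @param v an [nv_volume].
#' @return numeric length-3, `dim * spacing`.
#' @export
volume_extent <- function(v) dim(v$data) * v$spacing

# mm coordinates of all voxel centres of a mask's TRUE voxels, N x 3
mask_points <- function(m) {
  idx <- which(m$data)
  if (length(idx) == 0) return(matrix(numeric(0), 0, 3))
  d <- dim(m$data)
  i <- (idx - 1L) %% d[1]
  j <- ((idx - 1L) %/% d[1]) %% d[2]
  k <- (idx - 1L) %/% (d[1] * d[2])
  cbind(m$origin[1] + i * m$spacing[1],
        m$origin[2] + j * m$spacing[2],
        m$origin[3] + k * m$spacing[3])
}

#' Dice overlap of two masks
#'
#' `2|A ∩ B| / (|A| + |B|)`, in \[0, 1\].
#'
#' @param a,b [nv_mask] objects on the same grid.
#' @return numeric scalar.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a$data), dim(b$data)))
  sa <- sum(a$data); sb <- sum(b$data)
  if (sa + sb == 0) stop("both masks empty: Dice undefined", call. = FALSE)
  2 * sum(a$data & b$data) / (sa + sb)
}

#' Left-right flip of a volume or mask
#'
#' Reverses the first (x) axis, the sagittal left-right direction in this
#' package's axial-stack convention.  An involution: flipping twice returns
#' the original object.
#'
#' @param v an [nv_volume] or [nv_mask].
#' @return Object of the same class.
#' @export
flip_lr <- function(v) {
  stopifnot(inherits(v, "nv_volume"))
  out <- v
  out$data <- v$data[dim(v$data)[1]:1, , , drop = FALSE]
  out
}
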