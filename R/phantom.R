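# Synthetic ball-and-socket joint phantoms with analytically known negative
# volumes.  A condyle (ball + cylindrical neck) articulates under a slab
# bone carrying a hemispherical socket of radius (condyle_radius + gap); the
# joint space is the upper hemispherical shell between them, whose volume
# and surface area have closed forms.  Left/right pairs are exact mirror
# images up to a controllable right-side gap scaling (the asymmetry factor).

#' Phantom specification
#'
#' All lengths in mm; intensities in arbitrary units (three tissue plateaus
#' plus Gaussian noise).  `asymmetry_factor` scales the right-side gap.
#'
#' @param condyle_radius ball radius.
#' @param gap joint-space thickness (left side).
#' @param neck_radius,neck_length cylindrical neck below the ball.
#' @param slab_thickness socket slab above the joint; must contain the full
#'   hemispherical socket (`>= condyle_radius + scaled gap`).
#' @param socket_lip cylindrical lip of the socket wrapping below the
#'   equatorial plane (mm); confines the joint space laterally.
#' @param slab_radius lateral radius of the socket slab disc (mm);
#'   `NULL` (default) uses socket radius + 3.  A finite slab keeps the two
#'   joints of a head phantom spatially separate, as real joints are.
#' @param intensity_bone,intensity_soft,intensity_air tissue plateaus.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param asymmetry_factor right-side gap multiplier (> 0; 1 = symmetric).
#' @param grid_shape voxels per axis of a single-joint grid.
#' @param spacing isotropic voxel size (mm).
#' @param seed RNG seed for the noise realization.
#' @return `nv_phantomspec` list.
#' @export
phantom_spec <- function(condyle_radius = 6, gap = 2, neck_radius = 2.5,
                         neck_length = 4, slab_thickness = 10,
                         socket_lip = 2, slab_radius = NULL,
                         intensity_bone = 0.85, intensity_soft = 0.35,
                         intensity_air = 0.05, noise_sd = 0.03,
                         asymmetry_factor = 1, grid_shape = c(48, 48, 48),
                         spacing = 0.5, seed = 1) {
  if (gap <= 0) stop("gap must be > 0", call. = FALSE)
  if (condyle_radius <= neck_radius)
    stop("condyle_radius must exceed neck_radius", call. = FALSE)
  if (asymmetry_factor <= 0) stop("asymmetry_factor must be > 0", call. = FALSE)
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  # the slab must contain the full hemispherical socket, otherwise the joint
  # space is open at the top and the closed-form shell volume does not apply
  if (slab_thickness < condyle_radius + gap * max(1, asymmetry_factor))
    stop("slab_thickness must be >= condyle_radius + scaled gap (socket containment)",
         call. = FALSE)
  structure(list(condyle_radius = condyle_radius, gap = gap,
                 neck_radius = neck_radius, neck_length = neck_length,
                 slab_thickness = slab_thickness, socket_lip = socket_lip,
                 slab_radius = slab_radius,
                 intensity_bone = intensity_bone,
                 intensity_soft = intensity_soft,
                 intensity_air = intensity_air, noise_sd = noise_sd,
                 asymmetry_factor = asymmetry_factor,
                 grid_shape = as.integer(grid_shape), spacing = spacing,
                 seed = as.integer(seed)),
            class = "nv_phantomspec")
}

#' Closed-form negative volume and surface area of a phantom
#'
#' The negative volume is the upper hemispherical shell between the condyle
#' (radius r) and the socket (radius r + g): volume
#' `(2/3) pi ((r+g)^3 - r^3)`; its surface consists of the outer and inner
#' hemispheres plus the equatorial annulus:
#' `2 pi (r+g)^2 + 2 pi r^2 + pi ((r+g)^2 - r^2)`.
#'
#' @param spec an [phantom_spec].
#' @param side `"left"` or `"right"` (the right gap is scaled by the
#'   asymmetry factor).
#' @return list with `volume` (mm^3), `area` (mm^2) and the effective `gap`.
#' @export
phantom_analytic <- function(spec, side = c("left", "right")) {
  side <- match.arg(side)
  g <- spec$gap * if (side == "right") spec$asymmetry_factor else 1
  r <- spec$condyle_radius
  R <- r + g
  list(volume = 2 / 3 * pi * (R^3 - r^3),
       area = 2 * pi * R^2 + 2 * pi * r^2 + pi * (R^2 - r^2),
       gap = g)
}

# voxel-centre coordinate arrays for a grid
.grid_coords <- function(dims, spacing, origin) {
  list(x = origin[1] + (seq_len(dims[1]) - 1) * spacing[1],
       y = origin[2] + (seq_len(dims[2]) - 1) * spacing[2],
       z = origin[3] + (seq_len(dims[3]) - 1) * spacing[3])
}

# build the geometry masks of one joint on a grid; centre at `ctr` (mm)
.joint_masks <- function(dims, spacing, origin, ctr, spec, gap_eff) {
  co <- .grid_coords(dims, rep(spacing, 3), origin)
  r <- spec$condyle_radius; R <- r + gap_eff
  dx2 <- (co$x - ctr[1])^2
  dy2 <- (co$y - ctr[2])^2
  dz <- co$z - ctr[3]
  r2 <- outer(outer(dx2, dy2, `+`), dz^2, `+`)
  rho2 <- outer(outer(dx2, dy2, `+`), rep(0, dims[3]), `+`)
  zarr <- outer(outer(rep(0, dims[1]), rep(0, dims[2]), `+`), dz, `+`)
  lip <- spec$socket_lip %||% 0
  srad <- spec$slab_radius %||% (R + 3)
  ball <- r2 <= r^2
  neck <- rho2 <= spec$neck_radius^2 &
    zarr <= 0 & zarr >= -(r + spec$neck_length)
  mc <- ball | neck
  # finite slab disc above the equator, plus a short lip wrapping below it
  slab <- rho2 <= srad^2 &
    ((zarr >= 0 & zarr <= spec$slab_thickness & r2 > R^2) |
       (zarr < 0 & zarr >= -lip & rho2 > R^2))
  tb <- slab
  gapm <- r2 > r^2 & r2 <= R^2 & zarr >= 0
  list(mc = mc, tb = tb, gap = gapm)
}

.phantom_intensity <- function(masks, spec) {
  v <- array(spec$intensity_soft, dim(masks$mc))
  v[masks$gap] <- spec$intensity_air
  v[masks$mc | masks$tb] <- spec$intensity_bone
  v
}

#' Generate a single ball-and-socket joint phantom
#'
#' @param spec an [phantom_spec].
#' @param side `"left"` or `"right"`; the right side uses
#'   `gap * asymmetry_factor`.
#' @return `nv_phantom` list: `volume` ([nv_volume]), `mc_mask`, `tb_mask`,
#'   `gap_mask` ([nv_mask]), `mc_mesh`, `tb_mesh` ([nv_mesh]),
#'   `analytic_negative_volume`, `analytic_negative_area`, `clip_plane`
#'   (point + normal of the equatorial plane), `side`, `spec`.
#' @export
make_joint_phantom <- function(spec, side = c("left", "right")) {
  stopifnot(inherits(spec, "nv_phantomspec"))
  side <- match.arg(side)
  an <- phantom_analytic(spec, side)
  dims <- spec$grid_shape; sp <- spec$spacing
  ext <- dims * sp
  R <- spec$condyle_radius + an$gap
  srad <- spec$slab_radius %||% (R + 3)
  need_xy <- 2 * max(R, srad) + 4 * sp
  need_z <- spec$neck_length + spec$condyle_radius + spec$slab_thickness + 4 * sp
  if (ext[1] < need_xy || ext[2] < need_xy || ext[3] < need_z)
    stop(sprintf(
      "phantom geometry does not fit the grid (need %.1f x %.1f x %.1f mm, have %.1f x %.1f x %.1f mm)",
      need_xy, need_xy, need_z, ext[1], ext[2], ext[3]), call. = FALSE)
  origin <- c(0, 0, 0)
  ctr <- c(ext[1] / 2, ext[2] / 2,
           2 * sp + spec$neck_length + spec$condyle_radius)
  masks <- .joint_masks(dims, sp, origin, ctr, spec, an$gap)
  v <- .phantom_intensity(masks, spec)
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(spec$seed)
    v <- v + array(stats::rnorm(length(v), sd = spec$noise_sd), dim(v))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  vol <- nv_volume(v, rep(sp, 3), origin)
  mc <- nv_mask(masks$mc, rep(sp, 3), origin)
  tb <- nv_mask(masks$tb, rep(sp, 3), origin)
  structure(list(
    volume = vol, mc_mask = mc, tb_mask = tb,
    gap_mask = nv_mask(masks$gap, rep(sp, 3), origin),
    mc_mesh = mask_to_mesh(mc, smooth_radius = 1),
    tb_mesh = mask_to_mesh(tb, smooth_radius = 1),
    analytic_negative_volume = an$volume,
    analytic_negative_area = an$area,
    clip_plane = list(point = ctr, normal = c(0, 0, 1)),
    centre = ctr, side = side, spec = spec), class = "nv_phantom")
}

#' Generate a two-sided "head" phantom
#'
#' Embeds a left and a right joint mirror-symmetrically about the
#' mid-sagittal plane of a double-width grid.  With `asymmetry_factor = 1`
#' the two halves are exact mirror reflections; otherwise the right gap is
#' scaled.
#'
#' @param spec an [phantom_spec]; the head grid is
#'   `c(2, 1, 1) * grid_shape`.
#' @return `nv_head_phantom` list: `volume`, per-side `left`/`right`
#'   (`nv_phantom`-like, masks on the full head grid), `boxes`
#'   (ground-truth [bounding_box]es) and `mid_plane`.
#' @export
make_head_phantom <- function(spec) {
  stopifnot(inherits(spec, "nv_phantomspec"))
  half <- spec$grid_shape
  sp <- spec$spacing
  dims <- c(2L * half[1], half[2], half[3])
  origin <- c(0, 0, 0)
  ctr_l <- c(half[1] * sp / 2, half[2] * sp / 2,
             2 * sp + spec$neck_length + spec$condyle_radius)
  halves <- list()
  for (side in c("left", "right")) {
    an <- phantom_analytic(spec, side)
    R <- spec$condyle_radius + an$gap
    srad <- max(R, spec$slab_radius %||% (R + 3))
    if (2 * srad + 4 * sp > half[1] * sp || 2 * srad + 4 * sp > half[2] * sp ||
        spec$neck_length + spec$condyle_radius + spec$slab_thickness +
          4 * sp > half[3] * sp)
      stop("joints do not fit their half grids (overlap or clipping)",
           call. = FALSE)
    m <- .joint_masks(half, sp, origin, ctr_l, spec, an$gap)
    if (side == "right")
      m <- lapply(m, function(a) a[half[1]:1, , , drop = FALSE])
    halves[[side]] <- list(masks = m, analytic = an)
  }
  glue <- function(field) {
    full <- array(FALSE, dims)
    full[seq_len(half[1]), , ] <- halves$left$masks[[field]]
    full[half[1] + seq_len(half[1]), , ] <- halves$right$masks[[field]]
    full
  }
  mc <- glue("mc"); tb <- glue("tb"); gp <- glue("gap")
  v <- .phantom_intensity(list(mc = mc, tb = tb, gap = gp), spec)
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(spec$seed)
    v <- v + array(stats::rnorm(length(v), sd = spec$noise_sd), dim(v))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  vol <- nv_volume(v, rep(sp, 3), origin)
  sides <- list()
  boxes <- list()
  for (i in 1:2) {
    side <- c("left", "right")[i]
    off <- if (side == "left") 0L else half[1]
    sel <- function(a) {
      full <- array(FALSE, dims)
      full[off + seq_len(half[1]), , ] <- a
      full
    }
    m <- halves[[side]]$masks
    mcm <- nv_mask(sel(m$mc), rep(sp, 3), origin)
    tbm <- nv_mask(sel(m$tb), rep(sp, 3), origin)
    an <- halves[[side]]$analytic
    ctr <- ctr_l
    # index mirroring i -> 2h+1-i maps mm coordinate x to (dims-1)*sp - x
    if (side == "right") ctr[1] <- (dims[1] - 1) * sp - ctr_l[1]
    tb_box <- .tight_box(sel(m$mc | m$tb))
    boxes[[side]] <- bounding_box(tb_box$min, tb_box$max, side)
    sides[[side]] <- structure(list(
      volume = vol, mc_mask = mcm, tb_mask = tbm,
      gap_mask = nv_mask(sel(m$gap), rep(sp, 3), origin),
      mc_mesh = mask_to_mesh(mcm, smooth_radius = 1),
      tb_mesh = mask_to_mesh(tbm, smooth_radius = 1),
      analytic_negative_volume = an$volume,
      analytic_negative_area = an$area,
      clip_plane = list(point = ctr, normal = c(0, 0, 1)),
      centre = ctr, side = side, spec = spec), class = "nv_phantom")
  }
  structure(list(volume = vol, left = sides$left, right = sides$right,
                 boxes = boxes,
                 mid_plane = list(point = c((dims[1] - 1) * sp / 2, 0, 0),
                                  normal = c(1, 0, 0)),
                 spec = spec), class = "nv_head_phantom")
}

#' Generate a reproducible phantom cohort
#'
#' Parameters are drawn uniformly from the given ranges; a fixed number of
#' phantoms receive an asymmetric right joint (gap scaled by a factor drawn
#' from `asymmetry_range`), the rest are symmetric.  Metadata records the
#' drawn parameters, the asymmetric flag and the analytic per-side negative
#' volumes.
#'
#' @param n cohort size (>= 1).
#' @param spec_ranges named list; each of `condyle_radius`, `gap`,
#'   `neck_radius`, `neck_length`, `slab_thickness`, `noise_sd` may be a
#'   scalar or a `c(min, max)` range.  `grid_shape` and `spacing` are taken
#'   as-is.
#' @param seed cohort seed.
#' @param n_asymmetric how many phantoms get an asymmetric right joint.
#' @param asymmetry_range `c(min, max)` factor range for those phantoms.
#' @return list with `phantoms` (list of [make_head_phantom] results) and
#'   `metadata` (tibble).
#' @export
make_cohort <- function(n, spec_ranges = list(), seed = 1, n_asymmetric = 0,
                        asymmetry_range = c(1.2, 1.4)) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (n_asymmetric > n) stop("n_asymmetric exceeds n", call. = FALSE)
  base <- phantom_spec(grid_shape = c(52, 52, 56))
  draw <- function(name) {
    r <- spec_ranges[[name]] %||% base[[name]]
    if (length(r) == 1) return(rep(r, n))
    if (length(r) != 2 || r[2] < r[1]) stop(sprintf("bad range for %s", name),
                                            call. = FALSE)
    stats::runif(n, r[1], r[2])
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  pars <- list()
  for (nm in c("condyle_radius", "gap", "neck_radius", "neck_length",
               "slab_thickness", "noise_sd"))
    pars[[nm]] <- draw(nm)
  asym_ids <- if (n_asymmetric > 0) sort(sample(n, n_asymmetric)) else integer(0)
  af <- rep(1, n)
  if (n_asymmetric > 0)
    af[asym_ids] <- stats::runif(n_asymmetric, asymmetry_range[1],
                                 asymmetry_range[2])
  seeds <- sample.int(2^30, n)
  phantoms <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- phantom_spec(
      condyle_radius = pars$condyle_radius[i], gap = pars$gap[i],
      neck_radius = pars$neck_radius[i], neck_length = pars$neck_length[i],
      slab_thickness = pars$slab_thickness[i],
      noise_sd = pars$noise_sd[i], asymmetry_factor = af[i],
      grid_shape = spec_ranges$grid_shape %||% base$grid_shape,
      spacing = spec_ranges$spacing %||% base$spacing, seed = seeds[i])
    phantoms[[i]] <- make_head_phantom(sp)
    al <- phantom_analytic(sp, "left"); ar <- phantom_analytic(sp, "right")
    rows[[i]] <- tibble::tibble(
      id = i, condyle_radius = pars$condyle_radius[i], gap = pars$gap[i],
      asymmetry_factor = af[i], asymmetric = i %in% asym_ids,
      noise_sd = pars$noise_sd[i], seed = seeds[i],
      volume_left = al$volume, volume_right = ar$volume,
      area_left = al$area, area_right = ar$area,
      s_lr_analytic = max(al$area, ar$area) / min(al$area, ar$area))
  }
  list(phantoms = phantoms, metadata = do.call(rbind, rows))
}

#' Write a phantom to disk (NIfTI + STL + JSON metadata)
#'
#' @param ph an `nv_phantom` from [make_joint_phantom] (or one side of a
#'   head phantom).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(ph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(ph$volume, file.path(dir, "volume.nii.gz"))
  write_volume(ph$mc_mask, file.path(dir, "mc_mask.nii.gz"))
  write_volume(ph$tb_mask, file.path(dir, "tb_mask.nii.gz"))
  write_mesh_stl(ph$mc_mesh, file.path(dir, "mc_mesh.stl"))
  write_mesh_stl(ph$tb_mesh, file.path(dir, "tb_mesh.stl"))
  meta <- list(side = ph$side,
               analytic_negative_volume = ph$analytic_negative_volume,
               analytic_negative_area = ph$analytic_negative_area,
               clip_plane = ph$clip_plane, spec = unclass(ph$spec))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
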