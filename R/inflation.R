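# The core negative-volume construction: inflate the condyle mesh along its
# vertex normals, regularized by Laplacian smoothing, until it is stopped by
# the socket-bone surface; clip the mandibular neck with a capped plane cut;
# and extract the negative volume as a Boolean difference of solids.

#' Inflation parameters
#'
#' @param step displacement per iteration along the vertex normal (mm).
#' @param max_iters iteration cap.
#' @param laplacian_weight smoothing weight `lambda` in \[0, 1): each
#'   iteration moves every free vertex to
#'   `(1 - lambda) v + lambda mean(neighbours)`.  `lambda = 1` collapses the
#'   mesh towards neighbour means and is rejected.
#' @param collision_tolerance stand-off distance from the bounding surface
#'   (mm) at which a vertex freezes.
#' @param sdf_resolution grid resolution (max voxels along the longest axis)
#'   of the signed-distance field of the bounding mesh.
#' @return `nv_inflationparams` list.
#' @export
inflation_params <- function(step = 0.1, max_iters = 500,
                             laplacian_weight = 0.2,
                             collision_tolerance = 0.05,
                             sdf_resolution = 128) {
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  if (max_iters < 1) stop("max_iters must be >= 1", call. = FALSE)
  if (laplacian_weight < 0 || laplacian_weight >= 1)
    stop("laplacian_weight must lie in [0, 1); 1 collapses the mesh",
         call. = FALSE)
  if (collision_tolerance < 0) stop("collision_tolerance must be >= 0",
                                    call. = FALSE)
  structure(list(step = step, max_iters = as.integer(max_iters),
                 laplacian_weight = laplacian_weight,
                 collision_tolerance = collision_tolerance,
                 sdf_resolution = as.integer(sdf_resolution)),
            class = "nv_inflationparams")
}

# signed distance field of a watertight mesh solid on a regular grid:
# positive outside, negative inside.  Returns a sampler closure.
.mesh_sdf <- function(bound, pad, resolution) {
  bb <- mesh_bbox(bound)
  lo <- bb[1, ] - pad; hi <- bb[2, ] + pad
  sp <- max(hi - lo) / resolution
  dims <- pmax(4L, as.integer(ceiling((hi - lo) / sp)) + 1L)
  inside <- cpp_voxelize(bound$vertices, bound$faces, dims,
                         rep(sp, 3), lo)
  d_in <- cpp_edt3d(inside, dims, rep(sp, 3))
  d_out <- cpp_edt3d(!inside, dims, rep(sp, 3))
  sdf <- d_in - d_out  # >0 outside the solid, <0 inside
  sdf[!is.finite(sdf) & sdf > 0] <- max(hi - lo)   # empty solid: far outside
  sdf[!is.finite(sdf) & sdf < 0] <- -max(hi - lo)
  far <- max(hi - lo)
  function(p) {
    xs <- (p[, 1] - lo[1]) / sp + 1
    ys <- (p[, 2] - lo[2]) / sp + 1
    zs <- (p[, 3] - lo[3]) / sp + 1
    .sample_grid(sdf, xs, ys, zs, fill = far)
  }
}

#' Inflate a mesh along vertex normals inside a bounding surface
#'
#' Each iteration displaces every free vertex by `step` along its area-
#' weighted vertex normal, then applies Laplacian smoothing.  A vertex whose
#' motion would bring it within `collision_tolerance` of the bounding solid
#' (signed distance, inside/outside by ray parity) is frozen at the contact
#' point, found by bisection along its motion segment.  Iteration stops when
#' every vertex is frozen or `max_iters` is reached.
#'
#' @param mc the mesh to inflate (watertight, outward-oriented); it must not
#'   intersect the bounding solid initially.
#' @param bound the bounding surface ([nv_mesh]), or `NULL` for unconstrained
#'   inflation.
#' @param p an [inflation_params].
#' @param trace record per-iteration enclosed volume and frozen fraction.
#' @return The inflated [nv_mesh]; with `trace = TRUE`, attribute `"trace"`
#'   holds a tibble (iteration, volume, frozen_fraction).
#' @export
inflate <- function(mc, bound = NULL, p = inflation_params(), trace = FALSE) {
  stopifnot(inherits(mc, "nv_mesh"), inherits(p, "nv_inflationparams"))
  if (!is_watertight(mc)) stop("mesh to inflate is not watertight", call. = FALSE)
  mc <- ensure_outward(mc, "auto")
  sdf <- NULL
  if (!is.null(bound)) {
    if (!is_watertight(bound)) stop("bounding mesh is not watertight",
                                    call. = FALSE)
    bound <- ensure_outward(bound, "auto")
    pad <- p$step * p$max_iters / 4 + 2
    sdf <- .mesh_sdf(bound, pad = min(pad, 50), resolution = p$sdf_resolution)
    if (any(sdf(mc$vertices) < 0))
      stop("mesh intersects the bounding solid before inflation", call. = FALSE)
  }
  v <- mc$vertices
  faces <- mc$faces
  nvert <- nrow(v)
  E <- mesh_edges(mc)
  deg <- tabulate(E[, 1], nbins = nvert)
  frozen <- rep(FALSE, nvert)
  tr <- if (trace) vector("list", p$max_iters) else NULL
  tol <- p$collision_tolerance
  vnormals <- function(v) {
    u <- v[faces[, 2], , drop = FALSE] - v[faces[, 1], , drop = FALSE]
    w <- v[faces[, 3], , drop = FALSE] - v[faces[, 1], , drop = FALSE]
    n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
    vn <- matrix(0, nvert, 3)
    for (j in 1:3) {
      s <- rowsum(n, faces[, j])
      ids <- as.integer(rownames(s))
      vn[ids, ] <- vn[ids, ] + s
    }
    vn / pmax(sqrt(rowSums(vn^2)), 1e-300)
  }
  for (it in seq_len(p$max_iters)) {
    n <- vnormals(v)
    free <- which(!frozen)
    if (length(free) == 0) break
    prop <- v
    prop[free, ] <- v[free, ] + p$step * n[free, ]
    if (!is.null(sdf)) {
      d <- sdf(prop[free, , drop = FALSE])
      hit <- which(d < tol)
      if (length(hit) > 0) {
        gi <- free[hit]
        # bisect t in [0, step] so that sdf(v + t n) ~ tol
        t_lo <- rep(0, length(gi)); t_hi <- rep(p$step, length(gi))
        for (b in 1:8) {
          t_mid <- (t_lo + t_hi) / 2
          pm <- v[gi, , drop = FALSE] + t_mid * n[gi, , drop = FALSE]
          below <- sdf(pm) < tol
          t_hi[below] <- t_mid[below]
          t_lo[!below] <- t_mid[!below]
        }
        prop[gi, ] <- v[gi, , drop = FALSE] + t_lo * n[gi, , drop = FALSE]
        frozen[gi] <- TRUE
      }
    }
    v <- prop
    # Laplacian regularization on still-free vertices
    if (p$laplacian_weight > 0) {
      free <- which(!frozen)
      if (length(free) > 0) {
        nb_sum <- rowsum(v[E[, 2], , drop = FALSE], E[, 1])
        mean_nb <- nb_sum[free, , drop = FALSE] / deg[free]
        cand <- (1 - p$laplacian_weight) * v[free, , drop = FALSE] +
          p$laplacian_weight * mean_nb
        if (!is.null(sdf)) {
          ok <- sdf(cand) >= tol
          v[free[ok], ] <- cand[ok, , drop = FALSE]
        } else v[free, ] <- cand
      }
    }
    if (trace) {
      u <- v[faces[, 2], , drop = FALSE] - v[faces[, 1], , drop = FALSE]
      w <- v[faces[, 3], , drop = FALSE] - v[faces[, 1], , drop = FALSE]
      nr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                  u[, 3] * w[, 1] - u[, 1] * w[, 3],
                  u[, 1] * w[, 2] - u[, 2] * w[, 1])
      tr[[it]] <- tibble::tibble(
        iteration = it,
        volume = sum(rowSums(v[faces[, 1], , drop = FALSE] * nr)) / 6,
        area = sum(sqrt(rowSums(nr^2))) / 2,
        frozen_fraction = mean(frozen))
    }
    if (all(frozen)) break
  }
  out <- nv_mesh(v, faces)
  if (trace) attr(out, "trace") <- do.call(rbind, tr[!vapply(tr, is.null, TRUE)])
  out
}

#' Clip a mesh with a plane and cap the cut
#'
#' Removes the half-space on the negative side of the plane normal and
#' closes each cut loop with a planar cap, so a watertight input stays
#' watertight.
#'
#' @param m a watertight [nv_mesh].
#' @param plane list with `point` and `normal` (mm).
#' @return Clipped [nv_mesh].
#' @export
clip_neck <- function(m, plane) {
  stopifnot(inherits(m, "nv_mesh"))
  nrm <- plane$normal / sqrt(sum(plane$normal^2))
  d <- as.vector((m$vertices - matrix(plane$point, nrow(m$vertices), 3,
                                      byrow = TRUE)) %*% nrm)
  # vertices exactly on the plane are nudged to the kept side so cuts never
  # pass through existing vertices (avoids degenerate faces on the cap)
  eps <- 1e-9 * max(1, diff(range(m$vertices)))
  d[abs(d) < eps] <- eps
  keep_v <- d >= 0
  if (all(keep_v)) return(m)
  if (!any(d > 0)) stop("clip plane removes the entire mesh", call. = FALSE)
  v <- m$vertices
  newv <- list()
  cutmap <- new.env(parent = emptyenv())
  cut_vertex <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    hit <- cutmap[[key]]
    if (!is.null(hit)) return(hit)
    t <- d[a] / (d[a] - d[b])
    pnt <- v[a, ] + t * (v[b, ] - v[a, ])
    newv[[length(newv) + 1]] <<- pnt
    id <- nrow(v) + length(newv)
    cutmap[[key]] <- id
    id
  }
  faces <- list()
  boundary <- list()  # directed edges on the cut, oriented with kept side
  for (i in seq_len(nrow(m$faces))) {
    tri <- m$faces[i, ]
    dk <- d[tri] >= 0
    nk <- sum(dk)
    if (nk == 3) { faces[[length(faces) + 1]] <- tri; next }
    if (nk == 0) next
    if (nk == 1) {
      k <- which(dk)
      t2 <- tri[c(k, k %% 3 + 1, (k + 1) %% 3 + 1)]  # kept vertex first
      a <- t2[1]; b <- t2[2]; cc <- t2[3]
      ab <- cut_vertex(a, b); ac <- cut_vertex(a, cc)
      faces[[length(faces) + 1]] <- c(a, ab, ac)
      boundary[[length(boundary) + 1]] <- c(ab, ac)
    } else {
      lone <- which(!dk)
      t2 <- tri[c(lone, lone %% 3 + 1, (lone + 1) %% 3 + 1)]  # dropped first
      cdrop <- t2[1]; a <- t2[2]; b <- t2[3]
      ca <- cut_vertex(cdrop, a); cb <- cut_vertex(cdrop, b)
      faces[[length(faces) + 1]] <- c(a, b, cb)
      faces[[length(faces) + 1]] <- c(a, cb, ca)
      boundary[[length(boundary) + 1]] <- c(cb, ca)
    }
  }
  allv <- rbind(v, do.call(rbind, newv))
  # close each boundary loop with a fan around its centroid
  if (length(boundary) > 0) {
    be <- do.call(rbind, boundary)
    nxt <- stats::setNames(be[, 2], as.character(be[, 1]))
    used <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(be))) {
      s <- be[i, 1]
      if (!is.null(used[[as.character(s)]])) next
      loop <- integer(0)
      cur <- s
      repeat {
        if (!is.null(used[[as.character(cur)]])) break
        used[[as.character(cur)]] <- TRUE
        loop <- c(loop, cur)
        nx <- nxt[as.character(cur)]
        if (is.na(nx)) break
        cur <- as.integer(nx)
        if (cur == s) break
      }
      if (length(loop) >= 3) {
        ctr <- colMeans(allv[loop, , drop = FALSE])
        allv <- rbind(allv, ctr)
        cid <- nrow(allv)
        # cap faces point along -normal (outward for the kept upper solid)
        for (j in seq_along(loop)) {
          a <- loop[j]; b <- loop[j %% length(loop) + 1]
          faces[[length(faces) + 1]] <- c(cid, b, a)
        }
      }
    }
  }
  f <- do.call(rbind, faces)
  keep_ids <- sort(unique(as.vector(f)))
  remap <- integer(nrow(allv)); remap[keep_ids] <- seq_along(keep_ids)
  nv_mesh(allv[keep_ids, , drop = FALSE],
          matrix(remap[f], ncol = 3))
}

# common voxel grid covering given meshes with a margin
.common_grid <- function(meshes, resolution, margin_frac = 0.03) {
  bbs <- lapply(meshes, mesh_bbox)
  lo <- do.call(pmin, lapply(bbs, function(b) b[1, ]))
  hi <- do.call(pmax, lapply(bbs, function(b) b[2, ]))
  pad <- max(hi - lo) * margin_frac
  lo <- lo - pad; hi <- hi + pad
  sp <- max(hi - lo) / resolution
  dims <- pmax(4L, as.integer(ceiling((hi - lo) / sp)) + 1L)
  list(dim = dims, spacing = rep(sp, 3), origin = lo)
}

#' Boolean difference / intersection of watertight solids
#'
#' Robust voxel-based Booleans: both solids are rasterized on a common fine
#' grid (ray-parity inside test), combined voxelwise, and the result is
#' re-meshed with marching tetrahedra.  Accuracy is set by `resolution`
#' (voxels along the longest axis of the joint bounding box).
#'
#' @param a,b watertight [nv_mesh] solids.
#' @param resolution grid resolution of the Boolean.
#' @return A watertight [nv_mesh] (empty mesh if the result is empty).
#' @export
boolean_difference <- function(a, b, resolution = 160) {
  stopifnot(inherits(a, "nv_mesh"), inherits(b, "nv_mesh"))
  if (!is_watertight(a) || !is_watertight(b))
    stop("boolean operands must be watertight", call. = FALSE)
  g <- .common_grid(list(a), resolution)
  ma <- cpp_voxelize(a$vertices, a$faces, g$dim, g$spacing, g$origin)
  mb <- cpp_voxelize(b$vertices, b$faces, g$dim, g$spacing, g$origin)
  res <- ma & !mb
  if (!any(res)) return(nv_mesh(matrix(numeric(0), 0, 3),
                                matrix(integer(0), 0, 3)))
  mask_to_mesh(nv_mask(res, g$spacing, g$origin))
}

#' @rdname boolean_difference
#' @export
boolean_intersection <- function(a, b, resolution = 160) {
  stopifnot(inherits(a, "nv_mesh"), inherits(b, "nv_mesh"))
  if (!is_watertight(a) || !is_watertight(b))
    stop("boolean operands must be watertight", call. = FALSE)
  g <- .common_grid(list(a), resolution)
  ma <- cpp_voxelize(a$vertices, a$faces, g$dim, g$spacing, g$origin)
  mb <- cpp_voxelize(b$vertices, b$faces, g$dim, g$spacing, g$origin)
  res <- ma & mb
  if (!any(res)) return(nv_mesh(matrix(numeric(0), 0, 3),
                                matrix(integer(0), 0, 3)))
  mask_to_mesh(nv_mask(res, g$spacing, g$origin))
}

#' Extract the negative volume of one joint
#'
#' The full step-E construction: inflate the condyle mesh inside the socket
#' bone, clip at the neck plane, and subtract the original condyle solid.
#'
#' @param mc_mesh condyle mesh (watertight).
#' @param tb_mesh socket-bone mesh (watertight) bounding the inflation.
#' @param clip_plane list with `point`, `normal`; the negative side of the
#'   normal (the neck side) is discarded.
#' @param params an [inflation_params].
#' @param resolution Boolean grid resolution.
#' @return list with `mesh` (negative-volume [nv_mesh]), `volume`, `area`,
#'   `inflated` mesh and the inflation `trace`.
#' @export
negative_volume <- function(mc_mesh, tb_mesh, clip_plane,
                            params = inflation_params(), resolution = 160) {
  infl <- inflate(mc_mesh, tb_mesh, params, trace = TRUE)
  clipped <- clip_neck(infl, clip_plane)
  neg <- boolean_difference(clipped, mc_mesh, resolution = resolution)
  mm <- mesh_measures(neg, require_watertight = FALSE)
  if (is.na(mm$volume)) {
    # voxel fallback: difference mask volume
    g <- .common_grid(list(clipped), resolution)
    ma <- cpp_voxelize(clipped$vertices, clipped$faces, g$dim, g$spacing, g$origin)
    mb <- cpp_voxelize(mc_mesh$vertices, mc_mesh$faces, g$dim, g$spacing, g$origin)
    mm$volume <- sum(ma & !mb) * prod(g$spacing)
  }
  list(mesh = neg, volume = mm$volume, area = mm$area, inflated = infl,
       trace = attr(infl, "trace"))
}
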