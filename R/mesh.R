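#' Triangle surface mesh in mm coordinates
#'
#' @param vertices N x 3 numeric matrix of vertex coordinates (mm).
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `nv_mesh`.
#' @export
nv_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates", call. = FALSE)
  structure(list(vertices = vertices, faces = faces), class = "nv_mesh")
}

#' @export
print.nv_mesh <- function(x, ...) {
  cat(sprintf("<nv_mesh> %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  if (nrow(x$faces) > 0) {
    wt <- is_watertight(x)
    m <- mesh_measures(x, require_watertight = FALSE)
    cat(sprintf("  watertight: %s; area %.4g mm^2%s\n", wt, m$area,
                if (wt) sprintf(", volume %.4g mm^3", m$volume) else ""))
  }
  invisible(x)
}

# directed edge table: M*3 rows of (from, to)
mesh_edges <- function(m) {
  f <- m$faces
  cbind(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1]))
}

#' Watertightness test
#'
#' A mesh is watertight (closed, consistently oriented, 2-manifold along
#' edges) when every undirected edge is shared by exactly two faces and each
#' directed edge appears exactly once.
#'
#' @param m an [nv_mesh].
#' @return logical scalar.
#' @export
is_watertight <- function(m) {
  if (nrow(m$faces) == 0) return(FALSE)
  e <- mesh_edges(m)
  nv <- nrow(m$vertices)
  dir_key <- (e[, 1] - 1) * nv + e[, 2]   # exact for nv < 2^26
  if (anyDuplicated(dir_key) > 0) return(FALSE)
  und_key <- sort((pmin(e[, 1], e[, 2]) - 1) * nv + pmax(e[, 1], e[, 2]))
  n <- length(und_key)
  if (n %% 2L != 0L) return(FALSE)
  odd <- und_key[seq(1, n, by = 2)]
  evn <- und_key[seq(2, n, by = 2)]
  all(odd == evn) && !anyDuplicated(odd)
}

# per-face normals (not normalized; magnitude = 2 * area) and areas
face_normals_raw <- function(m) {
  v <- m$vertices; f <- m$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}

#' Enclosed volume and surface area of a mesh
#'
#' Volume is the signed sum of tetrahedra spanned by the faces and the
#' origin (positive for outward orientation); area is the sum of triangle
#' areas.  Volume of an open mesh is undefined and raises an error unless
#' `require_watertight = FALSE`, in which case `volume` is `NA` for open
#' meshes.  An empty mesh has zero volume and area.
#'
#' @param m an [nv_mesh].
#' @param require_watertight error on open meshes when volume is requested.
#' @return list with elements `volume` (mm^3) and `area` (mm^2).
#' @export
mesh_measures <- function(m, require_watertight = TRUE) {
  if (nrow(m$faces) == 0) return(list(volume = 0, area = 0))
  n <- face_normals_raw(m)
  area <- sum(sqrt(rowSums(n^2))) / 2
  wt <- is_watertight(m)
  if (!wt && require_watertight)
    stop("mesh is not watertight: enclosed volume undefined", call. = FALSE)
  vol <- NA_real_
  if (wt) {
    v <- m$vertices; f <- m$faces
    a <- v[f[, 1], , drop = FALSE]
    vol <- sum(rowSums(a * n)) / 6
  }
  list(volume = vol, area = area)
}

#' Area-weighted vertex normals
#'
#' Each vertex normal is the average of its incident face normals weighted
#' by face area, normalized to unit length.  The mesh must be consistently
#' outward-oriented (positive signed volume); an inward-oriented watertight
#' mesh is reoriented automatically when `reorient = "auto"`, otherwise it
#' is an error.
#'
#' @param m a watertight [nv_mesh].
#' @param reorient `"error"` or `"auto"` for inward-oriented input.
#' @return N x 3 matrix of unit normals.
#' @export
vertex_normals <- function(m, reorient = c("error", "auto")) {
  reorient <- match.arg(reorient)
  m <- ensure_outward(m, action = reorient)
  n <- face_normals_raw(m)
  a2 <- sqrt(rowSums(n^2))
  if (any(a2 < 1e-14))
    stop(sprintf("mesh has %d degenerate (zero-area) faces", sum(a2 < 1e-14)),
         call. = FALSE)
  vn <- matrix(0, nrow(m$vertices), 3)
  for (j in 1:3) {
    for (k in 1:3) {
      acc <- rowsum(n[, k], m$faces[, j])
      vn[as.integer(rownames(acc)), k] <- vn[as.integer(rownames(acc)), k] + acc
    }
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

# flip winding if signed volume is negative; error or fix per `action`
ensure_outward <- function(m, action = c("error", "auto")) {
  action <- match.arg(action)
  if (!is_watertight(m)) stop("mesh is not watertight", call. = FALSE)
  vol <- mesh_measures(m)$volume
  if (vol >= 0) return(m)
  if (action == "error")
    stop("mesh is inward-oriented (negative signed volume)", call. = FALSE)
  nv_mesh(m$vertices, m$faces[, c(1, 3, 2)])
}

# vertex adjacency as a list of integer vectors
mesh_adjacency <- function(m) {
  e <- mesh_edges(m)
  split(e[, 2], e[, 1])
}

# axis-aligned bounding box, 2 x 3 matrix (min; max)
mesh_bbox <- function(m) {
  rbind(apply(m$vertices, 2, min), apply(m$vertices, 2, max))
}

#' Rigid/reflective transform of a mesh
#'
#' Applies `v -> v %*% t(R) + t`.  If `det(R) < 0` (a reflection) the face
#' winding is reversed so the mesh stays outward-oriented.
#'
#' @param m an [nv_mesh].
#' @param R 3 x 3 matrix.
#' @param t length-3 translation (mm).
#' @return Transformed `nv_mesh`.
#' @export
transform_mesh <- function(m, R = diag(3), t = c(0, 0, 0)) {
  v <- m$vertices %*% t(R) + matrix(t, nrow(m$vertices), 3, byrow = TRUE)
  f <- m$faces
  if (det(R) < 0) f <- f[, c(1, 3, 2), drop = FALSE]
  nv_mesh(v, f)
}

# unit-ish sphere mesh by subdividing an icosahedron; radius r, centre c
icosphere <- function(r = 1, center = c(0, 0, 0), subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdivisions)) {
    mid <- new.env()
    key <- function(a, b) paste(min(a, b), max(a, b))
    nf <- matrix(0L, 0, 3)
    getmid <- function(a, b) {
      k <- key(a, b)
      if (!is.null(mid[[k]])) return(mid[[k]])
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid[[k]] <- nrow(v)
      nrow(v)
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- getmid(a, b); bc <- getmid(b, cc); ca <- getmid(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  out <- nv_mesh(v * r + matrix(center, nrow(v), 3, byrow = TRUE), f)
  ensure_outward(out, "auto")
}

# axis-aligned box mesh (12 triangles), outward-oriented
box_mesh <- function(lo, hi) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # corners: 1:(---) 2:(+--) 3:(-+-) 4:(++-) 5:(--+) 6:(+-+) 7:(-++) 8:(+++)
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = lo, outward -z
    c(5, 6, 8), c(5, 8, 7),   # z = hi
    c(1, 2, 6), c(1, 6, 5),   # y = lo
    c(3, 7, 8), c(3, 8, 4),   # y = hi
    c(1, 5, 7), c(1, 7, 3),   # x = lo
    c(2, 4, 8), c(2, 8, 6))   # x = hi
  nv_mesh(v, f)
}
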