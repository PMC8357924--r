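#' Read a CT volume from NIfTI or a DICOM series
#'
#' NIfTI files (`.nii` / `.nii.gz`) are read through RNifti; a DICOM series
#' is a directory with one uncompressed explicit-VR little-endian file per
#' axial slice (the subset of the standard this package writes and reads).
#' Slices are stacked along z in order of their patient position; a
#' non-uniform slice pitch beyond `pitch_tol` (relative) is a format error
#' naming the offending gap.
#'
#' @param path file (NIfTI) or directory (DICOM series).
#' @param format `"auto"`, `"nifti"` or `"dicom"`.
#' @param pitch_tol relative tolerance on slice-pitch uniformity.
#' @return An [nv_volume]; voxel order (x, y, z), axial slices along z.
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom"),
                        pitch_tol = 1e-3) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file or directory: %s", path),
                               call. = FALSE)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom" else "nifti"
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[1:3]
    dat <- array(as.numeric(img), dim(img)[1:3])
    return(nv_volume(dat, spacing = abs(sp), origin = c(0, 0, 0)))
  }
  read_dicom_series(path, pitch_tol = pitch_tol)
}

#' Write a volume to NIfTI
#'
#' @param v an [nv_volume] or [nv_mask].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "nv_volume"))
  dat <- v$data
  if (is.logical(dat)) dat <- array(as.numeric(dat), dim(dat))
  img <- RNifti::asNifti(structure(dat, pixdim = v$spacing),
                         datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# STL (binary) mesh i/o
# ---------------------------------------------------------------------------

#' Read a binary STL file
#'
#' Vertices closer than `tol` are merged so the triangle soup becomes an
#' indexed mesh.
#'
#' @param path STL file.
#' @param tol vertex-merge tolerance in mm.
#' @return An [nv_mesh].
#' @export
read_mesh_stl <- function(path, tol = 1e-6) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  rec <- readBin(con, "raw", nf * 50)
  if (length(rec) < nf * 50) stop("truncated STL file", call. = FALSE)
  m <- matrix(rec, nrow = 50)
  tri <- vapply(seq_len(nf), function(i)
    readBin(m[13:48, i], "numeric", 9, size = 4, endian = "little"),
    numeric(9))
  pts <- matrix(as.numeric(tri), ncol = 3, byrow = TRUE)  # 3*nf x 3, xyz rows
  key <- paste(round(pts[, 1] / tol), round(pts[, 2] / tol), round(pts[, 3] / tol))
  uid <- match(key, unique(key))
  verts <- pts[!duplicated(uid), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  nv_mesh(verts, faces)
}

#' Write a mesh as binary STL
#'
#' @param m an [nv_mesh].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mesh_stl <- function(m, path) {
  stopifnot(inherits(m, "nv_mesh"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  nf <- nrow(m$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  n <- face_normals_raw(m)
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  v <- m$vertices
  for (i in seq_len(nf)) {
    writeBin(as.numeric(c(n[i, ], v[m$faces[i, 1], ], v[m$faces[i, 2], ],
                          v[m$faces[i, 3], ])), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Minimal DICOM series i/o (uncompressed, explicit VR little endian, one
# axial slice per file).  No installed R package reads DICOM, so the subset
# needed for axial CT stacks is implemented here; it is not a general reader.
# ---------------------------------------------------------------------------

dcm_tag <- function(group, element) c(group %% 256, group %/% 256,
                                      element %% 256, element %/% 256)

dcm_element <- function(group, element, vr, value) {
  head <- as.raw(dcm_tag(group, element))
  if (vr %in% c("OB", "OW")) {
    body <- value # already raw
    c(head, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(body), raw(), size = 4, endian = "little"), body)
  } else {
    body <- switch(vr,
      US = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
      DS = , IS = , LO = , CS = {
        s <- paste(value, collapse = "\\")
        if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
        charToRaw(s)
      },
      stop("unsupported VR"))
    c(head, charToRaw(vr),
      writeBin(length(body), raw(), size = 2, endian = "little"), body)
  }
}

#' Write a volume as a synthetic DICOM series
#'
#' One uncompressed explicit-VR little-endian file per axial slice, with the
#' geometry tags (`PixelSpacing`, `ImagePositionPatient`, `SliceThickness`)
#' that [read_volume] consumes.  Intensities are scaled to 16-bit unsigned
#' integers with a rescale slope/intercept.
#'
#' @param v an [nv_volume].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dicom_series <- function(v, dir) {
  stopifnot(inherits(v, "nv_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(v$data)
  lo <- min(v$data); hi <- max(v$data)
  slope <- if (hi > lo) (hi - lo) / 65535 else 1
  for (k in seq_len(d[3])) {
    sl <- v$data[, , k]
    px <- as.integer(round((sl - lo) / slope))
    # pixel data stored x-fastest; the paired reader uses the same layout
    pix <- writeBin(as.vector(px), raw(), size = 2, endian = "little")
    z <- v$origin[3] + (k - 1) * v$spacing[3]
    el <- c(
      dcm_element(0x0020, 0x0032, "DS",
                  sprintf("%.6f", c(v$origin[1], v$origin[2], z))),
      dcm_element(0x0020, 0x0037, "DS",
                  sprintf("%.1f", c(1, 0, 0, 0, 1, 0))),
      dcm_element(0x0028, 0x0002, "US", 1),
      dcm_element(0x0028, 0x0010, "US", d[2]),  # Rows (y)
      dcm_element(0x0028, 0x0011, "US", d[1]),  # Columns (x)
      dcm_element(0x0028, 0x0030, "DS",
                  sprintf("%.6f", c(v$spacing[2], v$spacing[1]))),
      dcm_element(0x0018, 0x0050, "DS", sprintf("%.6f", v$spacing[3])),
      dcm_element(0x0028, 0x0100, "US", 16),
      dcm_element(0x0028, 0x0101, "US", 16),
      dcm_element(0x0028, 0x0102, "US", 15),
      dcm_element(0x0028, 0x0103, "US", 0),
      dcm_element(0x0028, 0x1052, "DS", sprintf("%.9g", lo)),
      dcm_element(0x0028, 0x1053, "DS", sprintf("%.9g", slope)),
      dcm_element(0x7FE0, 0x0010, "OW", pix))
    con <- file(file.path(dir, sprintf("slice_%04d.dcm", k)), "wb")
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(el, con)
    close(con)
  }
  invisible(dir)
}

read_dicom_file <- function(path) {
  rw <- readBin(path, "raw", file.size(path))
  if (length(rw) < 132 || rawToChar(rw[129:132]) != "DICM")
    stop(sprintf("corrupt DICOM file (missing DICM magic): %s", path),
         call. = FALSE)
  pos <- 133L
  tags <- list()
  while (pos + 8 <= length(rw) + 1) {
    grp <- as.integer(rw[pos]) + 256L * as.integer(rw[pos + 1])
    ele <- as.integer(rw[pos + 2]) + 256L * as.integer(rw[pos + 3])
    vr <- rawToChar(rw[(pos + 4):(pos + 5)])
    if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
      len <- readBin(rw[(pos + 8):(pos + 11)], "integer", 1, size = 4,
                     endian = "little")
      val_at <- pos + 12L
    } else {
      len <- readBin(rw[(pos + 6):(pos + 7)], "integer", 1, size = 2,
                     endian = "little", signed = FALSE)
      val_at <- pos + 8L
    }
    key <- sprintf("%04x,%04x", grp, ele)
    val <- rw[val_at:(val_at + len - 1L)]
    tags[[key]] <- switch(vr,
      US = readBin(val, "integer", len / 2, size = 2, endian = "little",
                   signed = FALSE),
      DS = , IS = as.numeric(strsplit(trimws(rawToChar(val)), "\\\\")[[1]]),
      LO = , CS = trimws(rawToChar(val)),
      val)
    pos <- val_at + len
  }
  tags
}

read_dicom_series <- function(dir, pitch_tol = 1e-3) {
  files <- sort(list.files(dir, pattern = "\\.dcm$", full.names = TRUE))
  if (length(files) == 0) stop("no .dcm files in directory", call. = FALSE)
  slices <- lapply(files, read_dicom_file)
  need <- c("0028,0010", "0028,0011", "0028,0030", "0020,0032", "7fe0,0010")
  for (s in slices) if (!all(need %in% names(s)))
    stop("corrupt DICOM slice: required tags missing", call. = FALSE)
  zs <- vapply(slices, function(s) s[["0020,0032"]][3], numeric(1))
  ord <- order(zs)
  slices <- slices[ord]; zs <- zs[ord]
  nx <- slices[[1]][["0028,0011"]]; ny <- slices[[1]][["0028,0010"]]
  if (length(zs) > 1) {
    gaps <- diff(zs)
    pitch <- stats::median(gaps)
    bad <- which(abs(gaps - pitch) > pitch_tol * pitch)
    if (length(bad) > 0)
      stop(sprintf(
        "non-uniform slice spacing: gap %.6g mm between slices %d and %d (expected %.6g mm)",
        gaps[bad[1]], bad[1], bad[1] + 1, pitch), call. = FALSE)
  } else pitch <- slices[[1]][["0018,0050"]] %||% 1
  ps <- slices[[1]][["0028,0030"]]  # (row spacing = y, col spacing = x)
  dat <- array(0, c(nx, ny, length(slices)))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    px <- readBin(s[["7fe0,0010"]], "integer", nx * ny, size = 2,
                  endian = "little", signed = FALSE)
    slope <- (s[["0028,1053"]] %||% 1); icept <- (s[["0028,1052"]] %||% 0)
    dat[, , k] <- array(px * slope + icept, c(nx, ny))
  }
  org <- slices[[1]][["0020,0032"]]
  nv_volume(dat, spacing = c(ps[2], ps[1], pitch),
            origin = c(org[1], org[2], zs[1]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
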