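# File formats: NIfTI volumes/masks, STL/PLY meshes, JSON landmarks and
# plans, CSV/JSON study reports.

#' Read and write CT volumes (NIfTI)
#'
#' Volumes are stored as NIfTI-1 (.nii / .nii.gz) with the full affine
#' (spacing, origin, direction) in the sform, so geometry survives a
#' write/read round trip bit-exact to floating precision.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param vol a [ct_volume()].
#' @return `read_volume()`: a [ct_volume()]; writers return the path
#'   invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such volume file: %s", path), call. = FALSE)
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop(sprintf("unsupported volume format: %s (NIfTI .nii/.nii.gz expected)",
                 basename(path)), call. = FALSE)
  img <- RNifti::readNifti(path)
  xf <- unclass(RNifti::xform(img))[1:3, , drop = FALSE]
  spacing <- sqrt(colSums(xf[, 1:3]^2))
  direction <- sweep(xf[, 1:3], 2L, spacing, "/")
  ct_volume(array(as.numeric(img), dim(img)), spacing,
            origin = xf[, 4L], direction = direction)
}

nifti_affine <- function(x) {
  A <- diag(4)
  A[1:3, 1:3] <- x$direction %*% diag(x$spacing)
  A[1:3, 4L] <- x$origin
  A
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$voxels)
  img <- RNifti::`sform<-`(img, structure(nifti_affine(vol), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @param mask a [binary_mask()]; stored as 0/1 integers.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$voxels), dim(mask$voxels)))
  img <- RNifti::`sform<-`(img, structure(nifti_affine(mask), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @param reference a [ct_volume()] the mask must align with (geometry check).
#' @export
read_mask <- function(path, reference = NULL) {
  vol <- read_volume(path)
  if (!is.null(reference)) {
    if (!all(dim(vol$voxels) == dim(reference$voxels)) ||
        max(abs(vol$spacing - reference$spacing)) > 1e-6 ||
        max(abs(vol$origin - reference$origin)) > 1e-4)
      stop("mask geometry does not match the reference volume", call. = FALSE)
  }
  binary_mask(vol, vol$voxels > 0.5)
}

# ---- meshes (STL binary/ascii, PLY ascii) -----------------------------------

#' Read and write triangle meshes (STL, PLY)
#'
#' Binary and ASCII stereolithography (.stl) plus ASCII PLY (.ply).  STL
#' stores independent triangles; on read, vertices are merged exactly so
#' watertight surfaces stay watertight.  Region labels are not representable
#' in either format and are dropped on write.
#'
#' @param mesh a [bone_mesh()].
#' @param path file path; format chosen by extension.
#' @param format for STL: `"binary"` (default) or `"ascii"`.
#' @return `read_mesh()`: a [bone_mesh()]; writers return the path invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") {
    if (format == "binary") write_stl_binary(mesh, path) else write_stl_ascii(mesh, path)
  } else if (ext == "ply") {
    write_ply_ascii(mesh, path)
  } else stop(sprintf("unsupported mesh format: .%s (stl/ply expected)", ext),
              call. = FALSE)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such mesh file: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") read_stl(path)
  else if (ext == "ply") read_ply_ascii(path)
  else stop(sprintf("unsupported mesh format: .%s (stl/ply expected)", ext),
            call. = FALSE)
}

face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(n * n)); len[len < 1e-15] <- 1
  n / len
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  fn <- face_normals(mesh)
  v <- mesh$vertices; f <- mesh$faces
  # 12 floats + attribute count per facet
  block <- matrix(0, 12L, nf)
  block[1:3, ] <- t(fn)
  block[4:6, ] <- t(v[f[, 1L], , drop = FALSE])
  block[7:9, ] <- t(v[f[, 2L], , drop = FALSE])
  block[10:12, ] <- t(v[f[, 3L], , drop = FALSE])
  raw_floats <- writeBin(as.numeric(block), raw(), size = 4L, endian = "little")
  fl <- matrix(raw_floats, nrow = 48L)
  attrib <- matrix(as.raw(0L), nrow = 2L, ncol = nf)
  writeBin(as.vector(rbind(fl, attrib)), con)
  invisible(path)
}

write_stl_ascii <- function(mesh, path) {
  fn <- face_normals(mesh)
  v <- mesh$vertices; f <- mesh$faces
  lines <- c("solid mesh",
             unlist(lapply(seq_len(nrow(f)), function(i) c(
               sprintf("  facet normal %.9g %.9g %.9g", fn[i, 1L], fn[i, 2L], fn[i, 3L]),
               "    outer loop",
               sprintf("      vertex %.9g %.9g %.9g",
                       v[f[i, c(1L, 2L, 3L)], 1L], v[f[i, c(1L, 2L, 3L)], 2L],
                       v[f[i, c(1L, 2L, 3L)], 3L]),
               "    endloop", "  endfacet"))),
             "endsolid mesh")
  writeLines(lines, path)
  invisible(path)
}

merge_triangle_soup <- function(tri_verts) {
  key <- apply(tri_verts, 1L, function(r) paste(r, collapse = "_"))
  uk <- !duplicated(key)
  verts <- tri_verts[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  bone_mesh(verts, faces)
}

read_stl <- function(path) {
  sz <- file.size(path)
  nf <- NA_integer_
  if (sz >= 84L) {
    con <- file(path, "rb")
    invisible(readBin(con, "raw", n = 80L))
    nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    close(con)
  }
  if (is.na(nf) || sz != 84 + 50 * as.numeric(nf)) {
    # ascii variant
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    if (!length(vl) || length(vl) %% 3L != 0L)
      stop(sprintf("cannot parse STL file: %s", basename(path)), call. = FALSE)
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
    return(merge_triangle_soup(nums))
  }
  con <- file(path, "rb"); on.exit(close(con))
  invisible(readBin(con, "raw", n = 84L))
  rest <- readBin(con, "raw", n = nf * 50L)
  m <- matrix(rest, nrow = 50L)
  floats <- matrix(readBin(as.vector(m[1:48, , drop = FALSE]), "numeric",
                           n = 12L * nf, size = 4L, endian = "little"),
                   nrow = 12L)
  tv <- matrix(0, 3L * nf, 3L)
  tv[seq(1L, 3L * nf, 3L), ] <- t(floats[4:6, , drop = FALSE])
  tv[seq(2L, 3L * nf, 3L), ] <- t(floats[7:9, , drop = FALSE])
  tv[seq(3L, 3L * nf, 3L), ] <- t(floats[10:12, , drop = FALSE])
  merge_triangle_soup(tv)
}

write_ply_ascii <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(c(hdr,
               sprintf("%.12g %.12g %.12g", v[, 1L], v[, 2L], v[, 3L]),
               sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L)),
             path)
  invisible(path)
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("not an ascii PLY file", call. = FALSE)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1L]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1L]))
  vb <- do.call(rbind, lapply(strsplit(trimws(lines[endh + seq_len(nv)]), "\\s+"),
                              function(p) as.numeric(p[1:3])))
  fb <- do.call(rbind, lapply(strsplit(trimws(lines[endh + nv + seq_len(nf)]), "\\s+"),
                              function(p) as.integer(p[2:4]) + 1L))
  bone_mesh(vb, fb)
}

# ---- landmarks and plans (JSON) ---------------------------------------------

required_physeal <- c("craniomedial", "craniolateral", "caudomedial", "caudolateral")

#' Read and write landmark files (JSON)
#'
#' Schema: `side` (`"left"`/`"right"`), `points` (named xyz triples; the
#' four physeal-scar names are required, `condyle_medial` /
#' `condyle_lateral` optional), optional `acetabular` with per-side
#' `cranial` / `caudal` border points.
#'
#' @param path JSON file path.
#' @param lm a [landmark_set()].
#' @return `read_landmarks()`: a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such landmark file: %s", path),
                               call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- j$points
  missing <- setdiff(required_physeal, names(pts))
  if (length(missing))
    stop(sprintf("landmark file %s is missing required point(s): %s",
                 basename(path), paste(missing, collapse = ", ")), call. = FALSE)
  get <- function(nm) if (nm %in% names(pts)) vec3(unlist(pts[[nm]])) else NULL
  ac <- NULL
  if (!is.null(j$acetabular))
    ac <- lapply(j$acetabular, function(s) lapply(s, function(p) vec3(unlist(p))))
  landmark_set(get("craniomedial"), get("craniolateral"),
               get("caudomedial"), get("caudolateral"),
               condyle_medial = get("condyle_medial"),
               condyle_lateral = get("condyle_lateral"),
               acetabular = ac,
               side = if (is.null(j$side)) "right" else j$side)
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  pts <- list(craniomedial = lm$craniomedial, craniolateral = lm$craniolateral,
              caudomedial = lm$caudomedial, caudolateral = lm$caudolateral)
  if (!is.null(lm$condyle_medial)) pts$condyle_medial <- lm$condyle_medial
  if (!is.null(lm$condyle_lateral)) pts$condyle_lateral <- lm$condyle_lateral
  jsonlite::write_json(list(side = lm$side, points = pts,
                            acetabular = lm$acetabular),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize an osteotomy plan (JSON)
#'
#' Planes stored as point + normal, with the landmark provenance and the
#' chevron dihedral angle.
#'
#' @param plan an `osteotomy_plan`.
#' @param path JSON file path.
#' @return `read_plan()`: an `osteotomy_plan`.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "osteotomy_plan"))
  lm <- plan$landmarks
  jsonlite::write_json(list(
    plane_a = list(point = plan$plane_a$point, normal = plan$plane_a$normal),
    plane_b = list(point = plan$plane_b$point, normal = plan$plane_b$normal),
    dihedral_angle = plan$dihedral_angle,
    landmarks = list(side = lm$side, points = list(
      craniomedial = lm$craniomedial, craniolateral = lm$craniolateral,
      caudomedial = lm$caudomedial, caudolateral = lm$caudolateral))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lm <- landmark_set(unlist(j$landmarks$points$craniomedial),
                     unlist(j$landmarks$points$craniolateral),
                     unlist(j$landmarks$points$caudomedial),
                     unlist(j$landmarks$points$caudolateral),
                     side = j$landmarks$side)
  structure(list(
    plane_a = plane(unlist(j$plane_a$point), unlist(j$plane_a$normal)),
    plane_b = plane(unlist(j$plane_b$point), unlist(j$plane_b$normal)),
    ridge = line3(lm$caudomedial, lm$craniolateral - lm$caudomedial),
    dihedral_angle = j$dihedral_angle,
    landmarks = lm), class = "osteotomy_plan")
}
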