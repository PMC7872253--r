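# CT volumes in Hounsfield units: thresholding, binary morphology,
# donor-recipient gap segmentation/volumetry, and isosurface extraction.

#' CT volume container
#'
#' A scalar Hounsfield-unit voxel grid with physical-space metadata.  The
#' centre of voxel (1,1,1) sits at `origin`; voxel index steps map to
#' physical space through `direction %*% diag(spacing)` (mm).
#'
#' @param voxels 3D numeric array (HU).
#' @param spacing per-axis voxel spacing in mm (length 3, > 0).
#' @param origin physical position of the first voxel centre (mm).
#' @param direction 3x3 proper orthonormal direction cosine matrix.
#' @return object of class `"ct_volume"`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0), direction = diag(3)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be > 0 per axis", call. = FALSE)
  direction <- unname(as.matrix(direction))
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6 || det(direction) < 0)
    stop("direction matrix must be proper orthonormal", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = vec3(origin),
                 direction = direction), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume %dx%dx%d, spacing %.3gx%.3gx%.3g mm, HU [%g, %g]>\n",
              d[1L], d[2L], d[3L], x$spacing[1L], x$spacing[2L], x$spacing[3L],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

voxel_volume <- function(x) prod(x$spacing)

#' Binary mask sharing a CT volume's geometry
#'
#' @param parent a [ct_volume()] (or another `binary_mask`) providing the
#'   geometry.
#' @param voxels logical 3D array of the same dimensions.
#' @return object of class `"binary_mask"`.
#' @export
binary_mask <- function(parent, voxels) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  ref_dim <- dim(parent$voxels)
  if (!all(dim(voxels) == ref_dim))
    stop("mask dimensions do not match the parent volume", call. = FALSE)
  structure(list(voxels = (voxels != 0), spacing = parent$spacing,
                 origin = parent$origin, direction = parent$direction),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask %dx%dx%d, %d true voxels (%.1f mm^3)>\n",
              d[1L], d[2L], d[3L], sum(x$voxels), sum(x$voxels) * voxel_volume(x)))
  invisible(x)
}

#' Bone segmentation by HU thresholding
#'
#' Marks every voxel at or above `hu_min` (inclusive, bone-window practice;
#' default 300 HU keeps cortical/subchondral bone and excludes marrow and
#' soft tissue).
#'
#' @param vol a [ct_volume()].
#' @param hu_min inclusive lower HU bound; must lie in the CT sanity range
#'   -1024..4000.
#' @return a [binary_mask()].
#' @export
threshold_bone <- function(vol, hu_min = 300) {
  stopifnot(inherits(vol, "ct_volume"))
  if (hu_min < -1024 || hu_min > 4000)
    stop("hu_min outside the plausible HU range (-1024..4000)", call. = FALSE)
  binary_mask(vol, vol$voxels >= hu_min)
}

# shift a logical array by integer offset (d1, d2, d3), zero-filled
shift_array <- function(a, d) {
  dm <- dim(a)
  out <- array(FALSE, dm)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    if (d[k] >= 0) { dst[[k]] <- seq((1 + d[k]), dm[k]); src[[k]] <- seq(1, dm[k] - d[k]) }
    else { dst[[k]] <- seq(1, dm[k] + d[k]); src[[k]] <- seq(1 - d[k], dm[k]) }
    if (length(src[[k]]) == 0L) return(out)
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

ball_offsets <- function(radius_mm, spacing) {
  k <- pmax(0L, floor(radius_mm / spacing))
  g <- expand.grid(d1 = -k[1L]:k[1L], d2 = -k[2L]:k[2L], d3 = -k[3L]:k[3L])
  keep <- (g$d1 * spacing[1L])^2 + (g$d2 * spacing[2L])^2 +
    (g$d3 * spacing[3L])^2 <= radius_mm^2 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

#' Binary dilation by a physical radius
#'
#' Dilates a mask with an ellipsoidal (Euclidean, mm-true) structuring
#' element; the radius is converted to voxels per axis.
#'
#' @param mask a [binary_mask()].
#' @param radius_mm dilation radius in mm.
#' @return a [binary_mask()].
#' @export
dilate_mask <- function(mask, radius_mm) {
  offs <- ball_offsets(radius_mm, mask$spacing)
  out <- array(FALSE, dim(mask$voxels))
  for (r in seq_len(nrow(offs)))
    out <- out | shift_array(mask$voxels, offs[r, ])
  binary_mask(mask, out)
}

neighborhood26 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0L, , drop = FALSE]
}

# voxels of `mask` reachable (26-connectivity) from `seeds` (both logical arrays)
propagate_mask <- function(mask, seeds) {
  cur <- seeds & mask
  offs <- neighborhood26()
  repeat {
    grown <- cur
    for (r in seq_len(nrow(offs)))
      grown <- grown | shift_array(cur, offs[r, ])
    grown <- grown & mask
    if (!any(grown & !cur)) return(cur)
    cur <- grown
  }
}

count_components26 <- function(arr) {
  n <- 0L
  rest <- arr
  while (any(rest)) {
    seed <- array(FALSE, dim(rest))
    seed[which(rest)[1L]] <- TRUE
    comp <- propagate_mask(rest, seed)
    rest <- rest & !comp
    n <- n + 1L
  }
  n
}

#' Region of interest between two bones
#'
#' Builds the gap-search region as the intersection of the two bone masks'
#' dilations minus the bones themselves — the reproducible substitute for
#' manually outlining the interface region.
#'
#' @param donor_mask,recipient_mask disjoint [binary_mask()] objects.
#' @param dilation_mm dilation radius in mm (default 2).
#' @return a [binary_mask()] (possibly empty).
#' @export
roi_between_bones <- function(donor_mask, recipient_mask, dilation_mm = 2) {
  if (any(donor_mask$voxels & recipient_mask$voxels))
    stop("donor and recipient masks overlap", call. = FALSE)
  dd <- dilate_mask(donor_mask, dilation_mm)
  dr <- dilate_mask(recipient_mask, dilation_mm)
  binary_mask(donor_mask,
              dd$voxels & dr$voxels & !donor_mask$voxels & !recipient_mask$voxels)
}

#' Donor-recipient gap segmentation and volumetry
#'
#' Segments the interface gap: voxels inside the region of interest with
#' HU at or below `hu_max` (default 250 HU, inclusive).  When the donor and
#' recipient bone masks are supplied, the candidate voxels are restricted to
#' 26-connected components that touch both bone surfaces, replacing manual
#' cleanup of the thresholded gap.
#'
#' @param vol a [ct_volume()].
#' @param roi a [binary_mask()] delimiting the interface region (non-empty).
#' @param hu_max inclusive upper HU bound for gap tissue (default 250).
#' @param donor_mask,recipient_mask optional bone [binary_mask()] objects
#'   enabling the touch-both-bones component rule.
#' @return list of class `"gap_result"`: `mask` ([binary_mask()]), `volume`
#'   (mm^3), `component_count`, `voxel_count`.
#' @export
segment_gap <- function(vol, roi, hu_max = 250,
                        donor_mask = NULL, recipient_mask = NULL) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!any(roi$voxels)) stop("empty region of interest", call. = FALSE)
  cand <- roi$voxels & (vol$voxels <= hu_max)
  if (!is.null(donor_mask) && !is.null(recipient_mask) && any(cand)) {
    offs <- neighborhood26()
    touch <- function(bone) {
      grown <- bone$voxels
      for (r in seq_len(nrow(offs)))
        grown <- grown | shift_array(bone$voxels, offs[r, ])
      propagate_mask(cand, grown & cand)
    }
    cand <- touch(donor_mask) & touch(recipient_mask)
  }
  mask <- binary_mask(vol, cand)
  structure(list(mask = mask,
                 volume = sum(cand) * voxel_volume(vol),
                 component_count = count_components26(cand),
                 voxel_count = sum(cand)),
            class = "gap_result")
}

# ---- marching tetrahedra isosurface ----------------------------------------

# Freudenthal (Kuhn) 6-tet cube decomposition: translation-consistent, so the
# extracted surface is watertight across cube boundaries.
freudenthal_tets <- function() {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  lapply(seq_len(6L), function(i) {
    e <- diag(3)
    p0 <- c(0, 0, 0)
    p1 <- e[perms[i, 1L], ]
    p2 <- p1 + e[perms[i, 2L], ]
    p3 <- c(1, 1, 1)
    rbind(p0, p1, p2, p3)
  })
}

# triangle topology per inside-pattern, as rows of local-edge index pairs;
# edges are (vertex, vertex) pairs into the 4 tet vertices
tet_case_tris <- function(inside) {
  s <- which(inside); o <- which(!inside)
  if (length(s) == 0L || length(s) == 4L) return(NULL)
  if (length(s) == 1L) {
    v <- s
    return(list(rbind(c(v, o[1L]), c(v, o[2L]), c(v, o[3L]))))
  }
  if (length(s) == 3L) {
    w <- o
    return(list(rbind(c(s[1L], w), c(s[2L], w), c(s[3L], w))))
  }
  # two inside: quad (v1w1, v1w2, v2w2, v2w1) -> two triangles
  v1 <- s[1L]; v2 <- s[2L]; w1 <- o[1L]; w2 <- o[2L]
  q <- rbind(c(v1, w1), c(v1, w2), c(v2, w2), c(v2, w1))
  list(q[c(1L, 2L, 3L), , drop = FALSE], q[c(1L, 3L, 4L), , drop = FALSE])
}

# orientation sign per (tet, case): +1 keeps triangle order, -1 swaps, so the
# normal points from inside (true) toward outside (false)
tet_case_table <- local({
  tets <- freudenthal_tets()
  tab <- vector("list", 6L)
  for (ti in seq_len(6L)) {
    tv <- tets[[ti]]
    cases <- vector("list", 16L)
    for (code in 1:14) {
      inside <- as.logical(bitwAnd(code, c(1L, 2L, 4L, 8L)) > 0L)
      tris <- tet_case_tris(inside)
      if (is.null(tris)) next
      cin <- colMeans(tv[inside, , drop = FALSE])
      cout <- colMeans(tv[!inside, , drop = FALSE])
      fixed <- lapply(tris, function(tr) {
        mid <- (tv[tr[, 1L], , drop = FALSE] + tv[tr[, 2L], , drop = FALSE]) / 2
        n <- cross3(mid[2L, ] - mid[1L, ], mid[3L, ] - mid[1L, ])
        if (sum(n * (cout - cin)) < 0) tr[c(1L, 3L, 2L), , drop = FALSE] else tr
      })
      cases[[code + 1L]] <- fixed
    }
    tab[[ti]] <- cases
  }
  tab
})

#' Isosurface extraction from a binary mask
#'
#' Extracts a watertight triangulated surface at the 0.5 level of the
#' binarized voxel field using marching tetrahedra on the Freudenthal 6-tet
#' cube decomposition (translation-consistent, hence watertight), with
#' surface vertices at voxel-edge midpoints, mapped to physical coordinates.
#' Triangles are oriented outward (away from the true voxels).
#'
#' @param mask a non-empty [binary_mask()].
#' @return a [bone_mesh()] in physical (mm) coordinates.
#' @export
extract_surface <- function(mask) {
  if (!any(mask$voxels)) stop("cannot extract a surface from an empty mask",
                              call. = FALSE)
  a <- mask$voxels
  dm <- dim(a)
  pad <- array(FALSE, dm + 2L)
  pad[2:(dm[1L] + 1L), 2:(dm[2L] + 1L), 2:(dm[3L] + 1L)] <- a
  pd <- dim(pad)
  nx <- pd[1L]; ny <- pd[2L]; nz <- pd[3L]
  cx <- nx - 1L; cy <- ny - 1L; cz <- nz - 1L

  corner <- function(dx, dy, dz)
    pad[(1L + dx):(cx + dx), (1L + dy):(cy + dy), (1L + dz):(cz + dz)]
  csum <- array(0L, c(cx, cy, cz))
  vals <- vector("list", 8L)
  ci <- 0L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ci <- ci + 1L
    vals[[ci]] <- corner(dx, dy, dz)
    csum <- csum + vals[[ci]]
  }
  mixed <- which(csum > 0L & csum < 8L)
  if (!length(mixed)) stop("mask has no isosurface crossings", call. = FALSE)
  base <- arrayInd(mixed, c(cx, cy, cz))  # padded lattice coords of cube corner

  corner_code <- function(off) 1L + off[1L] + 2L * off[2L] + 4L * off[3L]
  tets <- freudenthal_tets()

  tri_keys <- list(); tri_n <- 0L
  key_coord <- list()
  M1 <- 2L * nx + 2L; M2 <- 2L * ny + 2L
  for (ti in seq_len(6L)) {
    tv <- tets[[ti]]
    v <- matrix(FALSE, length(mixed), 4L)
    for (k in 1:4) v[, k] <- vals[[corner_code(tv[k, ])]][mixed]
    code <- v[, 1L] + 2L * v[, 2L] + 4L * v[, 3L] + 8L * v[, 4L]
    for (cs in 1:14) {
      sel <- which(code == cs)
      if (!length(sel)) next
      tris <- tet_case_table[[ti]][[cs + 1L]]
      for (tr in tris) {
        # edge midpoint integer keys: 2*base + (tvA + tvB) per coordinate
        b2 <- 2L * base[sel, , drop = FALSE]
        kmat <- matrix(0, length(sel), 3L)
        coords <- vector("list", 3L)
        for (corner_i in 1:3) {
          sum_off <- tv[tr[corner_i, 1L], ] + tv[tr[corner_i, 2L], ]
          r1 <- b2[, 1L] + sum_off[1L]
          r2 <- b2[, 2L] + sum_off[2L]
          r3 <- b2[, 3L] + sum_off[3L]
          kmat[, corner_i] <- r1 + M1 * (r2 + M2 * r3)
          coords[[corner_i]] <- cbind(r1, r2, r3) / 2
        }
        tri_n <- tri_n + 1L
        tri_keys[[tri_n]] <- list(k = kmat, c = coords)
      }
    }
  }

  all_keys <- do.call(rbind, lapply(tri_keys, `[[`, "k"))
  flat_keys <- c(all_keys[, 1L], all_keys[, 2L], all_keys[, 3L])
  uk <- unique(flat_keys)
  vid <- match(flat_keys, uk)
  nfaces <- nrow(all_keys)
  faces <- cbind(vid[seq_len(nfaces)],
                 vid[nfaces + seq_len(nfaces)],
                 vid[2L * nfaces + seq_len(nfaces)])
  # coordinates per unique key (first occurrence); all_coords rows are grouped
  # per corner in the same order as flat_keys
  first <- match(uk, flat_keys)
  coord_by_corner <- rbind(
    do.call(rbind, lapply(tri_keys, function(t) t$c[[1L]])),
    do.call(rbind, lapply(tri_keys, function(t) t$c[[2L]])),
    do.call(rbind, lapply(tri_keys, function(t) t$c[[3L]])))
  verts_idx <- coord_by_corner[first, , drop = FALSE]
  # padded lattice index -> original 1-based voxel index: subtract 1 pad layer;
  # then physical via origin/direction/spacing (voxel (1,1,1) centre at origin)
  cont_idx <- verts_idx - 1
  phys <- sweep(cont_idx - 1, 2L, mask$spacing, "*") %*% t(mask$direction)
  phys <- sweep(phys, 2L, mask$origin, "+")
  bone_mesh(phys, faces)
}
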