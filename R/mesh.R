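# Triangulated bone surfaces: container, primitives, volume/watertightness,
# and plane clipping with deterministic capping (virtual osteotomy support).

#' Triangulated bone surface
#'
#' A `bone_mesh` holds a triangulated surface: an `n x 3` vertex matrix (mm),
#' an `m x 3` integer face matrix (1-based, counter-clockwise when viewed
#' from outside, i.e. outward normals), and optional per-vertex /
#' per-face region labels (`"head"`, `"neck"`, `"diaphysis"`, `"articular"`,
#' `"cut"`, ...).
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param vertex_labels optional character vector, length n.
#' @param face_labels optional character vector, length m.
#' @return object of class `"bone_mesh"`.
#' @export
bone_mesh <- function(vertices, faces, vertex_labels = NULL, face_labels = NULL) {
  vertices <- as_point_matrix(if (length(vertices)) vertices else matrix(0, 0L, 3L))
  faces <- matrix(as.integer(faces), ncol = 3L)
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  if (!is.null(vertex_labels)) stopifnot(length(vertex_labels) == nrow(vertices))
  if (!is.null(face_labels)) stopifnot(length(face_labels) == nrow(faces))
  structure(list(vertices = vertices, faces = faces,
                 vertex_labels = vertex_labels, face_labels = face_labels),
            class = "bone_mesh")
}

#' @export
print.bone_mesh <- function(x, ...) {
  cat(sprintf("<bone_mesh: %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  if (!is.null(x$vertex_labels))
    cat(sprintf(", regions: %s", paste(sort(unique(x$vertex_labels)), collapse = "/")))
  cat(">\n")
  invisible(x)
}

empty_mesh <- function() bone_mesh(matrix(0, 0L, 3L), matrix(0L, 0L, 3L))

mesh_is_empty <- function(mesh) nrow(mesh$faces) == 0L

#' Mesh volume, watertightness and bounding box
#'
#' `mesh_volume()` integrates the divergence theorem over outward-oriented
#' triangles (signed tetrahedron sum); `mesh_is_watertight()` checks that
#' every directed edge is matched by exactly one reversed partner;
#' `mesh_bbox()` returns the axis-aligned bounding box.
#'
#' @param mesh a [bone_mesh()].
#' @return volume in mm^3; a logical; a 2 x 3 matrix (min/max rows).
#' @export
mesh_volume <- function(mesh) {
  if (mesh_is_empty(mesh)) return(0)
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  d <- v[f[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * d[, 3L] - b[, 3L] * d[, 2L]) -
      a[, 2L] * (b[, 1L] * d[, 3L] - b[, 3L] * d[, 1L]) +
      a[, 3L] * (b[, 1L] * d[, 2L] - b[, 2L] * d[, 1L])) / 6
}

#' @rdname mesh_volume
#' @export
mesh_is_watertight <- function(mesh) {
  if (mesh_is_empty(mesh)) return(TRUE)
  f <- mesh$faces
  from <- c(f[, 1L], f[, 2L], f[, 3L])
  to   <- c(f[, 2L], f[, 3L], f[, 1L])
  key_fwd <- paste(from, to)
  key_rev <- paste(to, from)
  if (anyDuplicated(key_fwd)) return(FALSE)
  all(key_rev %in% key_fwd)
}

#' @rdname mesh_volume
#' @export
mesh_bbox <- function(mesh) {
  if (!nrow(mesh$vertices)) return(matrix(0, 2L, 3L))
  rbind(apply(mesh$vertices, 2L, min), apply(mesh$vertices, 2L, max))
}

bbox_diag <- function(mesh) {
  bb <- mesh_bbox(mesh)
  vnorm(bb[2L, ] - bb[1L, ])
}

#' Concatenate meshes into one multi-component surface
#'
#' @param ... [bone_mesh()] objects (or a single list of them).
#' @return a [bone_mesh()]; labels are preserved where all inputs carry them.
#' @export
combine_meshes <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1L]], "bone_mesh")) parts <- parts[[1L]]
  parts <- Filter(function(m) nrow(m$faces) > 0L, parts)
  if (!length(parts)) return(empty_mesh())
  nv <- 0L
  verts <- list(); faces <- list(); vl <- list(); fl <- list()
  has_vl <- all(vapply(parts, function(m) !is.null(m$vertex_labels), TRUE))
  has_fl <- all(vapply(parts, function(m) !is.null(m$face_labels), TRUE))
  for (m in parts) {
    verts[[length(verts) + 1L]] <- m$vertices
    faces[[length(faces) + 1L]] <- m$faces + nv
    if (has_vl) vl[[length(vl) + 1L]] <- m$vertex_labels
    if (has_fl) fl[[length(fl) + 1L]] <- m$face_labels
    nv <- nv + nrow(m$vertices)
  }
  bone_mesh(do.call(rbind, verts), do.call(rbind, faces),
            if (has_vl) unlist(vl) else NULL,
            if (has_fl) unlist(fl) else NULL)
}

#' @export
apply_transform.bone_mesh <- function(transform, x) {
  x$vertices <- x$vertices %*% t(transform$rotation) +
    matrix(transform$translation, nrow(x$vertices), 3L, byrow = TRUE)
  x
}

#' @export
reflect_across.bone_mesh <- function(pl, x) {
  x$vertices <- reflect_points(pl, x$vertices)
  # a reflection reverses orientation; flip winding to keep normals outward
  x$faces <- x$faces[, c(1L, 3L, 2L), drop = FALSE]
  x
}

# ---- primitive meshes -------------------------------------------------------

#' Primitive watertight meshes
#'
#' Parametric building blocks for synthetic bones and test scenes:
#' a latitude/longitude sphere, a capped cylinder between two points,
#' an axis-aligned box, and spherical-cap solids/shells (the acetabular
#' graft-bed geometry).  All are watertight with outward normals.
#'
#' @param center,radius sphere centre (mm) and radius (mm).
#' @param n_lon,n_lat tessellation counts (longitudes, latitude bands).
#' @param label optional region label applied to all vertices/faces.
#' @return a [bone_mesh()].
#' @export
sphere_mesh <- function(center = c(0, 0, 0), radius = 1, n_lon = 48L,
                        n_lat = 24L, label = "sphere") {
  center <- vec3(center)
  lat <- seq(0, pi, length.out = n_lat + 1L)
  lon <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  verts <- list(center + c(0, 0, radius))
  idx <- function(i, j) 1L + (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  for (i in seq_len(n_lat - 1L)) {
    th <- lat[i + 1L]
    for (j in seq_len(n_lon)) {
      verts[[length(verts) + 1L]] <-
        center + radius * c(sin(th) * cos(lon[j]), sin(th) * sin(lon[j]), cos(th))
    }
  }
  south <- length(verts) + 1L
  verts[[south]] <- center + c(0, 0, -radius)
  faces <- list()
  for (j in seq_len(n_lon))  # north fan
    faces[[length(faces) + 1L]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
  if (n_lat > 2L) for (i in seq_len(n_lat - 2L)) for (j in seq_len(n_lon)) {
    a <- idx(i, j); b <- idx(i, j + 1L); cc <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
    faces[[length(faces) + 1L]] <- c(a, cc, d)
    faces[[length(faces) + 1L]] <- c(a, d, b)
  }
  for (j in seq_len(n_lon))  # south fan
    faces[[length(faces) + 1L]] <- c(south, idx(n_lat - 1L, j + 1L), idx(n_lat - 1L, j))
  v <- do.call(rbind, verts)
  f <- do.call(rbind, faces)
  bone_mesh(v, f, rep(label, nrow(v)), rep(label, nrow(f)))
}

#' @rdname sphere_mesh
#' @param p0,p1 cylinder end points (mm); normals point outward, caps included.
#' @param side_label,cap_label labels for lateral-surface and cap
#'   vertices/faces (cap rim vertices are lateral).
#' @export
cylinder_mesh <- function(p0, p1, radius, n_lon = 48L, n_axial = 16L,
                          side_label = "side", cap_label = "cap") {
  p0 <- vec3(p0); p1 <- vec3(p1)
  ax <- unitize(p1 - p0)
  seed <- if (abs(ax[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitize(cross3(ax, seed)); w <- cross3(ax, u)
  lon <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  t <- seq(0, 1, length.out = n_axial + 1L)
  verts <- list(); labs <- character(0)
  for (i in seq_along(t)) for (j in seq_len(n_lon)) {
    verts[[length(verts) + 1L]] <-
      p0 + t[i] * (p1 - p0) + radius * (cos(lon[j]) * u + sin(lon[j]) * w)
    labs <- c(labs, side_label)
  }
  idx <- function(i, j) (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  c0 <- length(verts) + 1L; verts[[c0]] <- p0; labs <- c(labs, cap_label)
  c1 <- length(verts) + 1L; verts[[c1]] <- p1; labs <- c(labs, cap_label)
  faces <- list(); flabs <- character(0)
  for (i in seq_len(n_axial)) for (j in seq_len(n_lon)) {
    a <- idx(i, j); b <- idx(i, j + 1L); cc <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
    faces[[length(faces) + 1L]] <- c(a, b, d); flabs <- c(flabs, side_label)
    faces[[length(faces) + 1L]] <- c(a, d, cc); flabs <- c(flabs, side_label)
  }
  for (j in seq_len(n_lon)) {  # bottom cap (outward = -ax)
    faces[[length(faces) + 1L]] <- c(c0, idx(1L, j + 1L), idx(1L, j))
    flabs <- c(flabs, cap_label)
  }
  for (j in seq_len(n_lon)) {  # top cap (outward = +ax)
    faces[[length(faces) + 1L]] <- c(c1, idx(n_axial + 1L, j), idx(n_axial + 1L, j + 1L))
    flabs <- c(flabs, cap_label)
  }
  bone_mesh(do.call(rbind, verts), do.call(rbind, faces), labs, flabs)
}

#' @rdname sphere_mesh
#' @param lo,hi box corners (mm).
#' @export
box_mesh <- function(lo, hi, label = "box") {
  lo <- vec3(lo); hi <- vec3(hi)
  v <- as.matrix(expand.grid(x = c(lo[1L], hi[1L]), y = c(lo[2L], hi[2L]),
                             z = c(lo[3L], hi[3L])))
  # corner order: 1=(0,0,0) 2=(1,0,0) 3=(0,1,0) 4=(1,1,0) 5..8 top
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),    # bottom (z = lo), outward -z
    c(5, 6, 8), c(5, 8, 7),    # top, outward +z
    c(1, 2, 6), c(1, 6, 5),    # y = lo, outward -y
    c(3, 7, 8), c(3, 8, 4),    # y = hi
    c(1, 5, 7), c(1, 7, 3),    # x = lo
    c(2, 4, 8), c(2, 8, 6))    # x = hi
  bone_mesh(v, f, rep(label, 8L), rep(label, 12L))
}

#' @rdname sphere_mesh
#' @param axis cap symmetry axis (pole direction).
#' @param half_angle_deg polar half-opening of the cap (90 = hemisphere).
#' @param base_label label for the flat closing disk / annulus.
#' @export
spherical_cap_mesh <- function(center, radius, axis = c(0, 0, 1),
                               half_angle_deg = 90, n_lon = 48L, n_lat = 16L,
                               label = "articular", base_label = "cut") {
  center <- vec3(center); ax <- unitize(vec3(axis))
  seed <- if (abs(ax[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitize(cross3(ax, seed)); w <- cross3(ax, u)
  th_max <- half_angle_deg * pi / 180
  th <- seq(0, th_max, length.out = n_lat + 1L)
  lon <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  verts <- list(center + radius * ax); labs <- label
  for (i in seq_len(n_lat)) for (j in seq_len(n_lon)) {
    verts[[length(verts) + 1L]] <- center + radius *
      (cos(th[i + 1L]) * ax + sin(th[i + 1L]) * (cos(lon[j]) * u + sin(lon[j]) * w))
    labs <- c(labs, label)
  }
  idx <- function(i, j) 1L + (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  base_c <- length(verts) + 1L
  verts[[base_c]] <- center + radius * cos(th_max) * ax
  labs <- c(labs, base_label)
  faces <- list(); flabs <- character(0)
  for (j in seq_len(n_lon)) {
    faces[[length(faces) + 1L]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
    flabs <- c(flabs, label)
  }
  if (n_lat > 1L) for (i in seq_len(n_lat - 1L)) for (j in seq_len(n_lon)) {
    a <- idx(i, j); b <- idx(i, j + 1L); cc <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
    faces[[length(faces) + 1L]] <- c(a, cc, d); flabs <- c(flabs, label)
    faces[[length(faces) + 1L]] <- c(a, d, b); flabs <- c(flabs, label)
  }
  for (j in seq_len(n_lon)) {  # flat base, outward = -ax
    faces[[length(faces) + 1L]] <- c(base_c, idx(n_lat, j + 1L), idx(n_lat, j))
    flabs <- c(flabs, base_label)
  }
  bone_mesh(do.call(rbind, verts), do.call(rbind, faces), labs, flabs)
}

#' @rdname sphere_mesh
#' @param r_inner,r_outer shell radii (mm), `r_inner < r_outer`.
#' @export
spherical_shell_cap_mesh <- function(center, r_inner, r_outer, axis = c(0, 0, 1),
                                     half_angle_deg = 90, n_lon = 48L, n_lat = 16L,
                                     label = "articular", base_label = "cut") {
  stopifnot(r_inner > 0, r_outer > r_inner)
  center <- vec3(center); ax <- unitize(vec3(axis))
  seed <- if (abs(ax[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitize(cross3(ax, seed)); w <- cross3(ax, u)
  th_max <- half_angle_deg * pi / 180
  th <- seq(0, th_max, length.out = n_lat + 1L)
  lon <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  dirv <- function(i, j) cos(th[i]) * ax + sin(th[i]) *
    (cos(lon[j]) * u + sin(lon[j]) * w)
  # outer cap vertices: pole + rings; inner cap likewise; join at rim annulus
  build_cap <- function(r) {
    vs <- list(center + r * ax)
    for (i in 2L:(n_lat + 1L)) for (j in seq_len(n_lon))
      vs[[length(vs) + 1L]] <- center + r * dirv(i, j)
    do.call(rbind, vs)
  }
  vo <- build_cap(r_outer)
  vi <- build_cap(r_inner)
  n_cap <- nrow(vo)
  verts <- rbind(vo, vi)
  o_idx <- function(i, j) 1L + (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  i_idx <- function(i, j) n_cap + o_idx(i, j)
  faces <- list(); flabs <- character(0)
  add <- function(tri, lab) {
    faces[[length(faces) + 1L]] <<- tri
    flabs <<- c(flabs, lab)
  }
  for (j in seq_len(n_lon)) add(c(1L, o_idx(1L, j), o_idx(1L, j + 1L)), label)
  if (n_lat > 1L) for (i in seq_len(n_lat - 1L)) for (j in seq_len(n_lon)) {
    a <- o_idx(i, j); b <- o_idx(i, j + 1L); cc <- o_idx(i + 1L, j); d <- o_idx(i + 1L, j + 1L)
    add(c(a, cc, d), label); add(c(a, d, b), label)
  }
  # inner cap faces point inward (toward centre), i.e. reversed winding
  for (j in seq_len(n_lon)) add(c(n_cap + 1L, i_idx(1L, j + 1L), i_idx(1L, j)), label)
  if (n_lat > 1L) for (i in seq_len(n_lat - 1L)) for (j in seq_len(n_lon)) {
    a <- i_idx(i, j); b <- i_idx(i, j + 1L); cc <- i_idx(i + 1L, j); d <- i_idx(i + 1L, j + 1L)
    add(c(a, d, cc), label); add(c(a, b, d), label)
  }
  # rim annulus between outer and inner boundary rings, outward = -ax side
  for (j in seq_len(n_lon)) {
    a <- o_idx(n_lat, j); b <- o_idx(n_lat, j + 1L)
    ai <- i_idx(n_lat, j); bi <- i_idx(n_lat, j + 1L)
    add(c(a, bi, b), base_label); add(c(a, ai, bi), base_label)
  }
  f <- do.call(rbind, faces)
  labs <- rep(label, nrow(verts))
  bone_mesh(verts, f, labs, flabs)
}

# ---- plane clipping with capping -------------------------------------------

# deterministic 2D ear clipping of a simple polygon given by index loop;
# pts2 is k x 2 in loop order.  Returns triangle rows of loop positions.
ear_clip2d <- function(pts2) {
  k <- nrow(pts2)
  if (k < 3L) return(matrix(integer(0), 0L, 3L))
  area2 <- sum(pts2[, 1L] * (pts2[c(2:k, 1L), 2L] - pts2[c(k, 1:(k - 1L)), 2L]))
  reversed <- FALSE
  ord <- seq_len(k)
  if (area2 < 0) { ord <- rev(ord); reversed <- TRUE }
  p <- pts2[ord, , drop = FALSE]
  active <- seq_len(k)
  tris <- list()
  guard <- 0L
  cross2 <- function(o, a, b)
    (a[1L] - o[1L]) * (b[2L] - o[2L]) - (a[2L] - o[2L]) * (b[1L] - o[1L])
  while (length(active) > 3L && guard < 10L * k) {
    guard <- guard + 1L
    n <- length(active)
    clipped <- FALSE
    for (ii in seq_len(n)) {
      i0 <- active[(ii - 2L) %% n + 1L]
      i1 <- active[(ii - 1L) %% n + 1L]
      i2 <- active[ii %% n + 1L]
      cr <- cross2(p[i0, ], p[i1, ], p[i2, ])
      if (cr <= 1e-14) next
      others <- setdiff(active, c(i0, i1, i2))
      inside <- FALSE
      for (oo in others) {
        d1 <- cross2(p[i0, ], p[i1, ], p[oo, ])
        d2 <- cross2(p[i1, ], p[i2, ], p[oo, ])
        d3 <- cross2(p[i2, ], p[i0, ], p[oo, ])
        if (d1 > -1e-14 && d2 > -1e-14 && d3 > -1e-14) { inside <- TRUE; break }
      }
      if (inside) next
      tris[[length(tris) + 1L]] <- c(i0, i1, i2)
      active <- setdiff(active, i1)
      clipped <- TRUE
      break
    }
    if (!clipped) break
  }
  if (length(active) >= 3L) {
    # remaining polygon: deterministic fan (handles the convex tail and
    # any numerically degenerate leftovers)
    a0 <- active[1L]
    for (ii in 2L:(length(active) - 1L))
      tris[[length(tris) + 1L]] <- c(a0, active[ii], active[ii + 1L])
  }
  tr <- do.call(rbind, tris)
  tr <- matrix(ord[tr], ncol = 3L)
  if (reversed) tr <- tr[, c(1L, 3L, 2L), drop = FALSE]
  tr
}

#' Clip a watertight mesh with a plane
#'
#' Splits a watertight triangulated surface along a plane and returns the
#' requested side, closed ("capped") along the cut so the result is again
#' watertight.  Cut cross-section loops are triangulated by a deterministic
#' ear-clipping order; multiply-connected cross-sections (e.g. a shell cut
#' into an annulus) are capped loop-by-loop with orientation inherited from
#' the cut boundary, which keeps enclosed volume and ray-parity exact.
#' Cap faces and cap vertices are labelled `"cut"`.
#'
#' @param mesh a watertight [bone_mesh()].
#' @param pl a [plane()].
#' @param keep `"positive"` (the side the normal points to) or `"negative"`.
#' @param cap close the cut cross-section (default TRUE).
#' @param eps_rel on-plane classification tolerance, relative to the mesh
#'   bounding-box diagonal.
#' @return a [bone_mesh()] (possibly empty).
#' @export
clip_mesh_plane <- function(mesh, pl, keep = c("positive", "negative"),
                            cap = TRUE, eps_rel = 1e-9) {
  keep <- match.arg(keep)
  if (mesh_is_empty(mesh)) return(mesh)
  sgn <- if (keep == "positive") 1 else -1
  s <- plane_distance(pl, mesh$vertices) * sgn
  eps <- eps_rel * max(bbox_diag(mesh), 1)
  cls <- ifelse(s > eps, 1L, ifelse(s < -eps, -1L, 0L))

  f <- mesh$faces
  c1 <- cls[f[, 1L]]; c2 <- cls[f[, 2L]]; c3 <- cls[f[, 3L]]
  has_pos <- (c1 > 0L) | (c2 > 0L) | (c3 > 0L)
  has_neg <- (c1 < 0L) | (c2 < 0L) | (c3 < 0L)
  all_zero <- (c1 == 0L) & (c2 == 0L) & (c3 == 0L)
  # pure on-plane faces belong to the positive side only (so a repeated clip
  # with the same plane is idempotent and the two sides never double-count)
  keep_whole <- (!has_neg & !all_zero) | (all_zero & keep == "positive")
  split_face <- has_pos & has_neg
  drop_face <- !keep_whole & !split_face

  old_labels <- mesh$vertex_labels
  fl <- mesh$face_labels
  verts <- mesh$vertices
  vlab <- if (is.null(old_labels)) rep(NA_character_, nrow(verts)) else old_labels

  # intersection vertices, computed once per crossing undirected edge
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  new_idx <- new.env(parent = emptyenv())
  extra_verts <- list()
  get_cut_vertex <- function(a, b) {
    k <- edge_key(a, b)
    hit <- new_idx[[k]]
    if (!is.null(hit)) return(hit)
    lo <- min(a, b); hi <- max(a, b)
    t <- s[lo] / (s[lo] - s[hi])
    pverts <- verts[lo, ] + t * (verts[hi, ] - verts[lo, ])
    extra_verts[[length(extra_verts) + 1L]] <<- pverts
    id <- nrow(verts) + length(extra_verts)
    new_idx[[k]] <- id
    id
  }

  out_faces <- list(); out_flabs <- character(0)
  seg_from <- integer(0); seg_to <- integer(0)
  keep_idx <- which(keep_whole)
  if (length(keep_idx)) {
    out_faces <- as.list(as.data.frame(t(f[keep_idx, , drop = FALSE])))
    out_flabs <- if (is.null(fl)) rep(NA_character_, length(keep_idx)) else fl[keep_idx]
  }

  for (fi in which(split_face)) {
    tri <- f[fi, ]
    tcls <- cls[tri]
    poly <- integer(0)
    for (e in 1:3) {
      a <- tri[e]; b <- tri[e %% 3L + 1L]
      if (tcls[e] >= 0L) poly <- c(poly, a)
      if (tcls[e] * cls[b] < 0L) poly <- c(poly, get_cut_vertex(a, b))
    }
    if (length(poly) < 3L) next
    lab <- if (is.null(fl)) NA_character_ else fl[fi]
    for (ii in 2L:(length(poly) - 1L)) {
      out_faces[[length(out_faces) + 1L]] <- c(poly[1L], poly[ii], poly[ii + 1L])
      out_flabs <- c(out_flabs, lab)
    }
  }

  if (length(extra_verts)) {
    verts <- rbind(verts, do.call(rbind, extra_verts))
    vlab <- c(vlab, rep("cut", length(extra_verts)))
  }

  # cut boundary = directed wall edges with no reversed partner (the input
  # being watertight, these arise only along the plane)
  if (cap && length(out_faces)) {
    wf <- do.call(rbind, out_faces)
    ekey <- paste(c(wf[, 1L], wf[, 2L], wf[, 3L]), c(wf[, 2L], wf[, 3L], wf[, 1L]))
    rkey <- paste(c(wf[, 2L], wf[, 3L], wf[, 1L]), c(wf[, 1L], wf[, 2L], wf[, 3L]))
    open <- which(!(ekey %in% rkey))
    seg_from <- c(wf[, 1L], wf[, 2L], wf[, 3L])[open]
    seg_to <- c(wf[, 2L], wf[, 3L], wf[, 1L])[open]
  }

  if (cap && length(seg_from)) {
    # chain directed boundary edges into loops; cap traverses loops reversed
    # so cap edges oppose wall edges (strict watertightness)
    nxt <- new.env(parent = emptyenv())
    for (i in seq_along(seg_from)) nxt[[as.character(seg_from[i])]] <- seg_to[i]
    visited <- new.env(parent = emptyenv())
    # plane 2D basis
    nrm <- pl$normal
    seed <- if (abs(nrm[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    bu <- unitize(cross3(nrm, seed)); bv <- cross3(nrm, bu)
    for (start in seg_from) {
      sk <- as.character(start)
      if (!is.null(visited[[sk]])) next
      loop <- integer(0)
      cur <- start
      ok <- TRUE
      repeat {
        ck <- as.character(cur)
        if (!is.null(visited[[ck]])) { ok <- (cur == start && length(loop) >= 3L); break }
        visited[[ck]] <- TRUE
        loop <- c(loop, cur)
        nx <- nxt[[ck]]
        if (is.null(nx)) { ok <- FALSE; break }
        cur <- nx
        if (cur == start) break
      }
      if (!ok || length(loop) < 3L) next
      loop <- rev(loop)
      p2 <- cbind(verts[loop, , drop = FALSE] %*% bu,
                  verts[loop, , drop = FALSE] %*% bv)
      tr <- ear_clip2d(p2)
      if (nrow(tr)) for (ri in seq_len(nrow(tr))) {
        out_faces[[length(out_faces) + 1L]] <- loop[tr[ri, ]]
        out_flabs <- c(out_flabs, "cut")
      }
    }
  }

  if (!length(out_faces)) return(empty_mesh())
  fmat <- do.call(rbind, out_faces)
  used <- sort(unique(as.integer(fmat)))
  remap <- integer(nrow(verts)); remap[used] <- seq_along(used)
  fmat <- matrix(remap[fmat], ncol = 3L)
  bone_mesh(verts[used, , drop = FALSE], fmat,
            if (is.null(old_labels)) NULL else vlab[used], out_flabs)
}
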