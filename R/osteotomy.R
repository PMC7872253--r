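# Chevron osteotomy planning from physeal-scar landmarks, virtual
# osteotomies, graft thickness checks, and donor-to-recipient alignment.

#' Named anatomic landmark set
#'
#' The four physeal-scar points used to define the chevron osteotomy, the
#' two condylar points defining the transcondylar axis, and (optionally)
#' the cranial/caudal acetabular border points per side.
#'
#' @param craniomedial,craniolateral,caudomedial,caudolateral physeal-scar
#'   points (mm).
#' @param condyle_medial,condyle_lateral condylar points (mm), optional.
#' @param acetabular optional list with `left`/`right`, each a list with
#'   `cranial` and `caudal` border points.
#' @param side `"left"` or `"right"`.
#' @return object of class `"landmark_set"`.
#' @export
landmark_set <- function(craniomedial, craniolateral, caudomedial, caudolateral,
                         condyle_medial = NULL, condyle_lateral = NULL,
                         acetabular = NULL, side = c("right", "left")) {
  side <- match.arg(side)
  phys <- list(craniomedial = vec3(craniomedial),
               craniolateral = vec3(craniolateral),
               caudomedial = vec3(caudomedial),
               caudolateral = vec3(caudolateral))
  pm <- do.call(rbind, phys)
  dd <- as.matrix(stats::dist(pm))
  if (min(dd[upper.tri(dd)]) < 1e-9)
    stop("physeal landmarks must be pairwise distinct", call. = FALSE)
  combs <- utils::combn(4L, 3L)
  scale <- max(dd)
  for (k in seq_len(ncol(combs))) {
    tri <- pm[combs[, k], ]
    n <- cross3(tri[2L, ] - tri[1L, ], tri[3L, ] - tri[1L, ])
    if (vnorm(n) <= 1e-8 * scale^2)
      stop(sprintf("physeal landmarks %s are collinear",
                   paste(rownames(pm)[combs[, k]], collapse = ", ")),
           call. = FALSE)
  }
  structure(c(phys, list(
    condyle_medial = if (is.null(condyle_medial)) NULL else vec3(condyle_medial),
    condyle_lateral = if (is.null(condyle_lateral)) NULL else vec3(condyle_lateral),
    acetabular = acetabular, side = side)), class = "landmark_set")
}

physeal_matrix <- function(lm) {
  rbind(craniomedial = lm$craniomedial, craniolateral = lm$craniolateral,
        caudomedial = lm$caudomedial, caudolateral = lm$caudolateral)
}

#' @export
apply_transform.landmark_set <- function(transform, x) {
  tp <- function(p) if (is.null(p)) NULL else drop(apply_transform(transform, p))
  x$craniomedial <- tp(x$craniomedial); x$craniolateral <- tp(x$craniolateral)
  x$caudomedial <- tp(x$caudomedial); x$caudolateral <- tp(x$caudolateral)
  x$condyle_medial <- tp(x$condyle_medial); x$condyle_lateral <- tp(x$condyle_lateral)
  if (!is.null(x$acetabular))
    x$acetabular <- lapply(x$acetabular, function(s) lapply(s, tp))
  x
}

#' Chevron osteotomy plan from the physeal landmarks
#'
#' Builds the two converging osteotomy planes: a craniodistal-to-caudoproximal
#' plane through the craniomedial, caudomedial and craniolateral points, and
#' a cranioproximal-to-caudodistal plane through the caudomedial, caudolateral
#' and craniolateral points.  The two shared points (caudomedial,
#' craniolateral) define the chevron ridge line.  When `head_point` is given
#' (typically the femoral-head region centroid) both normals are oriented so
#' the head side is positive.
#'
#' @param lm a [landmark_set()].
#' @param head_point optional point on the femoral-head side (mm).
#' @return object of class `"osteotomy_plan"`: `plane_a`, `plane_b`, `ridge`
#'   ([line3()] through the shared landmarks), `dihedral_angle` (degrees,
#'   angle between the oriented normals), `landmarks`.
#' @export
chevron_planes <- function(lm, head_point = NULL) {
  stopifnot(inherits(lm, "landmark_set"))
  pa <- plane_from_points(lm$craniomedial, lm$caudomedial, lm$craniolateral)
  pb <- plane_from_points(lm$caudomedial, lm$caudolateral, lm$craniolateral)
  if (!is.null(head_point)) {
    hp <- vec3(head_point)
    if (plane_distance(pa, hp) < 0) pa$normal <- -pa$normal
    if (plane_distance(pb, hp) < 0) pb$normal <- -pb$normal
  }
  ridge <- line3(lm$caudomedial, lm$craniolateral - lm$caudomedial)
  dih <- acos(max(-1, min(1, sum(pa$normal * pb$normal)))) * 180 / pi
  structure(list(plane_a = pa, plane_b = pb, ridge = ridge,
                 dihedral_angle = dih, landmarks = lm),
            class = "osteotomy_plan")
}

#' @export
apply_transform.osteotomy_plan <- function(transform, x) {
  structure(list(plane_a = apply_transform(transform, x$plane_a),
                 plane_b = apply_transform(transform, x$plane_b),
                 ridge = apply_transform(transform, x$ridge),
                 dihedral_angle = x$dihedral_angle,
                 landmarks = apply_transform(transform, x$landmarks)),
            class = "osteotomy_plan")
}

#' Execute the virtual chevron osteotomy
#'
#' Clips a watertight bone mesh with both plan planes.  The graft is the
#' region on the positive (femoral-head) side of both planes; the remainder
#' is everything else.  Both outputs are capped to watertightness and the
#' volumes sum to the input volume.
#'
#' @param mesh a watertight [bone_mesh()].
#' @param plan an [chevron_planes()] result.
#' @return list with `graft` and `remainder` ([bone_mesh()] objects; the
#'   remainder may hold two components, one per plane).
#' @export
clip_mesh <- function(mesh, plan) {
  stopifnot(inherits(plan, "osteotomy_plan"))
  if (!mesh_is_watertight(mesh))
    stop("clip_mesh requires a watertight input mesh", call. = FALSE)
  pos_a <- clip_mesh_plane(mesh, plan$plane_a, "positive")
  neg_a <- clip_mesh_plane(mesh, plan$plane_a, "negative")
  graft <- clip_mesh_plane(pos_a, plan$plane_b, "positive")
  neg_b <- clip_mesh_plane(pos_a, plan$plane_b, "negative")
  if (mesh_is_empty(graft))
    warning("osteotomy planes do not isolate any graft; returning an empty graft")
  list(graft = graft, remainder = combine_meshes(neg_a, neg_b))
}

vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  n <- matrix(0, nrow(v), 3L)
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  fn <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])  # area-weighted
  for (k in 1:3) {
    acc <- rowsum(fn, group = f[, k])
    idx <- as.integer(rownames(acc))
    n[idx, ] <- n[idx, ] + acc
  }
  len <- sqrt(rowSums(n * n))
  len[len < 1e-15] <- 1
  n / len
}

#' Maximum subchondral thickness of a graft
#'
#' For every articular-region vertex, casts a ray along the inward surface
#' normal and measures the distance to the first cut-surface face; the
#' maximum over vertices is the graft's subchondral thickness.  Grafts are
#' kept below 8 mm to limit the transplanted marrow volume (immune load)
#' while retaining structural integrity (3-8 mm working band).
#'
#' @param graft a capped [bone_mesh()] whose cut faces are labelled `"cut"`.
#' @param articular_label vertex label of the articular region (default
#'   `"articular"`; any label present may be supplied, e.g. `"head"`).
#' @param limit_mm acceptance bound (default 8 mm).
#' @return list with `thickness` (mm), `thickness_ok` (`thickness < limit_mm`),
#'   and `n_articular`.
#' @export
max_subchondral_thickness <- function(graft, articular_label = "articular",
                                      limit_mm = 8) {
  if (mesh_is_empty(graft))
    return(list(thickness = 0, thickness_ok = TRUE, n_articular = 0L))
  if (is.null(graft$vertex_labels) || !any(graft$vertex_labels %in% articular_label))
    stop(sprintf("graft has no vertices labelled '%s'",
                 paste(articular_label, collapse = "/")), call. = FALSE)
  if (is.null(graft$face_labels) || !any(graft$face_labels == "cut"))
    stop("graft has no 'cut' faces to measure thickness against", call. = FALSE)
  vn <- vertex_normals(graft)
  art <- which(graft$vertex_labels %in% articular_label)
  cut_f <- graft$faces[graft$face_labels == "cut", , drop = FALSE]
  va <- graft$vertices[cut_f[, 1L], , drop = FALSE]
  e1 <- graft$vertices[cut_f[, 2L], , drop = FALSE] - va
  e2 <- graft$vertices[cut_f[, 3L], , drop = FALSE] - va
  best <- rep(NA_real_, length(art))
  for (i in seq_along(art)) {
    o <- graft$vertices[art[i], ]
    d <- -vn[art[i], ]  # inward
    # Moller-Trumbore against all cut faces at once
    pv <- cbind(d[2L] * e2[, 3L] - d[3L] * e2[, 2L],
                d[3L] * e2[, 1L] - d[1L] * e2[, 3L],
                d[1L] * e2[, 2L] - d[2L] * e2[, 1L])
    det <- rowSums(e1 * pv)
    ok <- abs(det) > 1e-12
    tv <- matrix(o, nrow(va), 3L, byrow = TRUE) - va
    u <- rowSums(tv * pv) / det
    qv <- cbind(tv[, 2L] * e1[, 3L] - tv[, 3L] * e1[, 2L],
                tv[, 3L] * e1[, 1L] - tv[, 1L] * e1[, 3L],
                tv[, 1L] * e1[, 2L] - tv[, 2L] * e1[, 1L])
    vv <- (qv[, 1L] * d[1L] + qv[, 2L] * d[2L] + qv[, 3L] * d[3L]) / det
    t <- rowSums(e2 * qv) / det
    hit <- ok & u >= -1e-9 & vv >= -1e-9 & (u + vv) <= 1 + 1e-9 & t > 1e-9
    if (any(hit)) best[i] <- min(t[hit])
  }
  thick <- if (all(is.na(best))) 0 else max(best, na.rm = TRUE)
  list(thickness = thick, thickness_ok = thick < limit_mm,
       n_articular = length(art))
}

#' Least-squares rigid superimposition of landmark sets
#'
#' Kabsch alignment of four (or more) corresponding points: the proper rigid
#' transform (rotation + translation, no scaling, no reflection) minimizing
#' the RMS deviation, mapping `src` onto `dst`.  If the optimal orthogonal
#' transform is a reflection the landmark correspondence is probably
#' mislabelled and an error is raised.
#'
#' @param src,dst corresponding point sets (n x 3, n >= 3, not collinear).
#' @return list with `transform` ([rigid_transform()]) and `rmsd` (mm).
#' @export
superimpose_landmarks <- function(src, dst) {
  s <- as_point_matrix(src); d <- as_point_matrix(dst)
  if (nrow(s) != nrow(d) || nrow(s) < 3L)
    stop("need >= 3 corresponding landmark pairs", call. = FALSE)
  cs <- colMeans(s); cd <- colMeans(d)
  sc <- sweep(s, 2L, cs); dc <- sweep(d, 2L, cd)
  if (svd(sc, nu = 0L)$d[2L] <= 1e-9 * max(svd(sc, nu = 0L)$d[1L], 1))
    stop("source landmarks are collinear; rotation is not identifiable", call. = FALSE)
  H <- crossprod(sc, dc)
  sv <- svd(H)
  R <- sv$v %*% t(sv$u)
  if (det(R) < 0)
    stop(paste("optimal alignment is a reflection: the landmark sets have",
               "opposite handedness (probable craniocaudal or side mislabeling)"),
         call. = FALSE)
  tr <- cd - drop(R %*% cs)
  moved <- sc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - dc)^2)))
  list(transform = rigid_transform(R, tr), rmsd = rmsd)
}

#' Donor-recipient interface fit in mesh space
#'
#' Symmetric nearest-neighbour distance statistics between the cut surfaces
#' of the transformed donor graft and the recipient bed: a mesh-space
#' preview of the CT gap that will remain after implantation.  Cut faces
#' (label `"cut"`) are sampled at their vertices and centroids.
#'
#' @param donor_graft,recipient_bed capped [bone_mesh()] objects with cut
#'   faces labelled `"cut"` (when no labels are present the whole surface
#'   is used).
#' @param transform optional [rigid_transform()] applied to the donor first.
#' @return list with `mean_separation`, `max_separation`, `rms_separation`
#'   (mm) and the sample counts.
#' @export
interface_fit <- function(donor_graft, recipient_bed, transform = NULL) {
  if (!is.null(transform)) donor_graft <- apply_transform(transform, donor_graft)
  cut_points <- function(mesh) {
    f <- mesh$faces
    if (!is.null(mesh$face_labels) && any(mesh$face_labels == "cut"))
      f <- f[mesh$face_labels == "cut", , drop = FALSE]
    v <- mesh$vertices
    rbind(v[unique(as.integer(f)), , drop = FALSE],
          (v[f[, 1L], , drop = FALSE] + v[f[, 2L], , drop = FALSE] +
             v[f[, 3L], , drop = FALSE]) / 3)
  }
  a <- cut_points(donor_graft); b <- cut_points(recipient_bed)
  if (!nrow(a) || !nrow(b)) stop("no cut-surface samples available", call. = FALSE)
  nn <- function(p, q) {
    # chunked squared-distance nearest neighbour (exact)
    qs <- rowSums(q * q)
    apply_chunks <- function(idx) {
      d2 <- outer(rowSums(p[idx, , drop = FALSE]^2), qs, "+") -
        2 * p[idx, , drop = FALSE] %*% t(q)
      sqrt(pmax(apply(d2, 1L, min), 0))
    }
    unlist(lapply(split(seq_len(nrow(p)), ceiling(seq_len(nrow(p)) / 512L)),
                  apply_chunks), use.names = FALSE)
  }
  d_ab <- nn(a, b); d_ba <- nn(b, a)
  all_d <- c(d_ab, d_ba)
  list(mean_separation = mean(all_d), max_separation = max(all_d),
       rms_separation = sqrt(mean(all_d^2)),
       n_donor = nrow(a), n_recipient = nrow(b))
}
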