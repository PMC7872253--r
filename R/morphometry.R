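# Femoral coordinate frame and the three alignment measurements
# (inclination, version, neck length) plus acetabular diameter.
#
# The anatomic frame is built from the fitted diaphyseal axis and the
# transcondylar axis, so every measurement is invariant to how the limb was
# posed in the scanner.  Conventions (fixed, documented, side-aware):
#   - inclination: unsigned angle between the frontal-plane projection of the
#     neck direction (pointing at the head) and the *distally* pointing
#     diaphyseal direction; ~135 degrees in a normal canine femur.
#   - version: signed angle between the transverse-plane projections of the
#     neck direction and the mediolateral axis; cranially directed neck
#     (anteversion) is positive on both sides.

#' Anatomic femoral coordinate frame
#'
#' Builds the orthonormal, right-handed femoral frame from the diaphyseal
#' axis (direction pointing proximally) and the transcondylar axis.  The
#' mediolateral axis is the component of (medial condyle - lateral condyle)
#' orthogonal to the diaphyseal axis; the craniocaudal axis completes the
#' right-handed triad and is flipped for left femora so that "cranial" means
#' the same thing on both sides.
#'
#' @param diaphyseal_axis a [line3()] whose direction points proximally.
#' @param condyle_medial,condyle_lateral condylar reference points (mm).
#' @param side `"left"` or `"right"`.
#' @return object of class `"femoral_frame"`: fields `origin`, `axis_prox`,
#'   `axis_ml`, `axis_cc`, `side`.
#' @export
build_femoral_frame <- function(diaphyseal_axis, condyle_medial, condyle_lateral,
                                side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(inherits(diaphyseal_axis, "line3"))
  prox <- diaphyseal_axis$direction
  tc <- vec3(condyle_medial) - vec3(condyle_lateral)
  ang <- acos(min(1, abs(sum(unitize(tc) * prox)))) * 180 / pi
  if (ang < 10)
    stop(sprintf(
      "ill-conditioned frame: transcondylar axis within %.1f deg of the diaphyseal axis",
      ang), call. = FALSE)
  ml <- unitize(tc - sum(tc * prox) * prox)
  cc <- cross3(prox, ml)
  if (side == "left") cc <- -cc
  structure(list(origin = diaphyseal_axis$point, axis_prox = prox,
                 axis_ml = ml, axis_cc = cc, side = side),
            class = "femoral_frame")
}

#' Femoral neck axis from head centre and neck surface points
#'
#' The neck axis is the line from the fitted femoral-head centre through the
#' centroid of the neck-region surface points, directed from the diaphysis
#' toward the head.
#'
#' @param head_center fitted head centre (mm).
#' @param neck_points >= 10 neck-region surface points.
#' @param diaphyseal_axis [line3()]; used only to orient the direction
#'   away from the shaft.
#' @return a [line3()] through `head_center` pointing at the head.
#' @export
compute_neck_axis <- function(head_center, neck_points, diaphyseal_axis = NULL) {
  head_center <- vec3(head_center)
  m <- as_point_matrix(neck_points)
  if (nrow(m) < 10L)
    stop("neck axis needs at least 10 neck-region points", call. = FALSE)
  ctr <- colMeans(m)
  d <- head_center - ctr
  if (vnorm(d) < 1e-9)
    stop("degenerate neck region: centroid coincides with the head centre",
         call. = FALSE)
  line3(head_center, d)
}

neck_direction <- function(neck_axis) neck_axis$direction

#' Femoral neck inclination
#'
#' Unsigned angle, in degrees, between the frontal-plane projection of the
#' neck direction and the distally pointing diaphyseal direction; range
#' (0, 180).
#'
#' @param frame a [build_femoral_frame()] result.
#' @param neck_axis a [line3()] pointing from shaft toward head.
#' @return inclination in degrees.
#' @export
compute_inclination <- function(frame, neck_axis) {
  abs(projected_angle(neck_direction(neck_axis), -frame$axis_prox, frame$axis_cc))
}

#' Femoral neck version (anteversion positive)
#'
#' Signed angle, in degrees, between the transverse-plane projections of the
#' neck direction and the mediolateral axis.  A cranially directed neck
#' (anteversion) is positive on both sides; retroversion is negative.
#'
#' @inheritParams compute_inclination
#' @return version in degrees.
#' @export
compute_version <- function(frame, neck_axis) {
  d <- neck_direction(neck_axis)
  a_ml <- sum(d * frame$axis_ml)
  a_cc <- sum(d * frame$axis_cc)
  if (sqrt(a_ml^2 + a_cc^2) < 1e-9)
    stop("undefined projection: neck direction is parallel to the diaphyseal axis",
         call. = FALSE)
  atan2(a_cc, a_ml) * 180 / pi
}

#' Femoral neck length
#'
#' Distance from the femoral-head centre to the point where the neck axis
#' meets the diaphyseal axis; for generically skew axes the closest-approach
#' point on the neck axis is used (the exact intersection when coplanar).
#'
#' @param head_center head centre (mm).
#' @param neck_axis,diaphyseal_axis [line3()] objects, non-parallel.
#' @return neck length in mm.
#' @export
compute_neck_length <- function(head_center, neck_axis, diaphyseal_axis) {
  ca <- closest_approach(neck_axis, diaphyseal_axis)
  vnorm(vec3(head_center) - ca$point_a)
}

#' Acetabular diameter, both sides
#'
#' Per-side Euclidean distance between the cranial and caudal acetabular
#' border points and the bilateral mean used for donor-recipient matching.
#'
#' @param left,right length-2 lists/pairs of points `cranial`, `caudal`.
#' @return list with `left_diameter`, `right_diameter`, `mean_diameter` (mm).
#' @export
acetabular_diameter <- function(left, right) {
  if (missing(left) || missing(right) || is.null(left) || is.null(right))
    stop("acetabular borders required for both sides", call. = FALSE)
  dia <- function(b) {
    p <- if (!is.null(b$cranial)) list(b$cranial, b$caudal) else b
    vnorm(vec3(p[[1L]]) - vec3(p[[2L]]))
  }
  l <- dia(left); r <- dia(right)
  list(left_diameter = l, right_diameter = r, mean_diameter = (l + r) / 2)
}

#' Full femoral morphometry from a labelled mesh
#'
#' Runs the measurement chain: best-fit sphere on head-region vertices,
#' best-fit cylinder axis on diaphysis-region vertices (directed toward the
#' head, i.e. proximally), neck axis through the neck-region centroid,
#' anatomic frame from the condylar landmarks, then inclination, version and
#' neck length.
#'
#' @param mesh a [bone_mesh()] with vertex labels containing `"head"`,
#'   `"neck"` and `"diaphysis"` regions.
#' @param condyle_medial,condyle_lateral condylar landmarks (mm).
#' @param side `"left"` or `"right"`.
#' @return object of class `"morphometry_result"`: `head_center`,
#'   `head_radius`, `head_rms`, `neck_axis`, `diaphyseal_axis`, `frame`,
#'   `inclination`, `version`, `neck_length`, `side`.
#' @export
measure_femur <- function(mesh, condyle_medial, condyle_lateral,
                          side = c("right", "left")) {
  side <- match.arg(side)
  if (is.null(mesh$vertex_labels))
    stop("measure_femur needs a mesh with vertex region labels", call. = FALSE)
  pick <- function(region) {
    v <- mesh$vertices[mesh$vertex_labels == region, , drop = FALSE]
    if (!nrow(v)) stop(sprintf("mesh has no '%s' region vertices", region),
                       call. = FALSE)
    v
  }
  head_fit <- fit_sphere(pick("head"))
  shaft <- fit_axis(pick("diaphysis"), proximal_hint = head_fit$center)
  neck <- compute_neck_axis(head_fit$center, pick("neck"), shaft)
  frame <- build_femoral_frame(shaft, condyle_medial, condyle_lateral, side)
  structure(list(
    head_center = head_fit$center,
    head_radius = head_fit$radius,
    head_rms = head_fit$rms,
    neck_axis = neck,
    diaphyseal_axis = shaft,
    frame = frame,
    inclination = compute_inclination(frame, neck),
    version = compute_version(frame, neck),
    neck_length = compute_neck_length(head_fit$center, neck, shaft),
    side = side), class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<morphometry_result [%s femur]>\n",
    "  head centre   : (%.2f, %.2f, %.2f) mm, radius %.2f mm (rms %.3f)\n",
    "  inclination   : %.1f deg\n  version       : %.1f deg\n",
    "  neck length   : %.1f mm\n"),
    x$side, x$head_center[1L], x$head_center[2L], x$head_center[3L],
    x$head_radius, x$head_rms, x$inclination, x$version, x$neck_length))
  invisible(x)
}
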