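# Coordinate-free geometric primitives and least-squares fitting.
#
# All coordinates live in a right-handed physical frame in millimetres;
# angles are returned in degrees, internal trigonometry is in radians.

#' Numeric 3-vector helpers
#'
#' Points and vectors are plain numeric vectors of length 3 (x, y, z), in mm
#' for points and dimensionless for directions.  `vec3()` validates and
#' strips names; `vnorm()` is the Euclidean norm; `unitize()` rescales to
#' unit length; `cross3()` is the right-handed cross product.
#'
#' @param x,a,b numeric length-3 vectors.
#' @return `vec3()`, `unitize()`, `cross3()`: numeric length-3 vectors;
#'   `vnorm()`: a scalar.
#' @keywords internal
#' @name vec3-helpers
NULL

#' @rdname vec3-helpers
#' @export
vec3 <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 3L || anyNA(x) || any(!is.finite(x)))
    stop("expected a finite numeric vector of length 3", call. = FALSE)
  unname(x)
}

#' @rdname vec3-helpers
#' @export
vnorm <- function(x) sqrt(sum(x * x))

#' @rdname vec3-helpers
#' @export
unitize <- function(x) {
  n <- vnorm(x)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  x / n
}

#' @rdname vec3-helpers
#' @export
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

as_point_matrix <- function(points) {
  if (is.matrix(points)) {
    if (ncol(points) != 3L) stop("point matrix must have 3 columns", call. = FALSE)
    m <- unname(points)
  } else if (is.list(points)) {
    m <- do.call(rbind, lapply(points, vec3))
  } else {
    m <- matrix(vec3(points), ncol = 3L)
  }
  storage.mode(m) <- "double"
  m
}

#' Oriented plane, line, and sphere constructors
#'
#' Light S3 containers used throughout the planning and morphometry code.
#' A `plane` is a base point plus unit normal, a `line3` a base point plus
#' unit direction, a `sphere` a centre plus positive radius.
#'
#' @param point,center numeric length-3 (mm).
#' @param normal,direction numeric length-3; normalized on construction.
#' @param radius positive scalar (mm).
#' @return objects of class `"plane"`, `"line3"`, `"sphere"`.
#' @export
plane <- function(point, normal) {
  structure(list(point = vec3(point), normal = unitize(vec3(normal))),
            class = "plane")
}

#' @rdname plane
#' @export
line3 <- function(point, direction) {
  structure(list(point = vec3(point), direction = unitize(vec3(direction))),
            class = "line3")
}

#' @rdname plane
#' @export
sphere <- function(center, radius) {
  radius <- as.numeric(radius)
  if (!is.finite(radius) || radius <= 0) stop("sphere radius must be > 0", call. = FALSE)
  structure(list(center = vec3(center), radius = radius), class = "sphere")
}

#' Signed distance of points to a plane
#'
#' @param pl a [plane()].
#' @param points point matrix / list / single point.
#' @return numeric vector of signed distances (mm), positive on the side the
#'   normal points to.
#' @export
plane_distance <- function(pl, points) {
  m <- as_point_matrix(points)
  drop((m - matrix(pl$point, nrow(m), 3L, byrow = TRUE)) %*% pl$normal)
}

#' Plane through three points
#'
#' Constructs the oriented plane through three non-collinear points.  The
#' normal follows the right-hand rule on (`p2 - p1`, `p3 - p1`): it is
#' invariant under cyclic permutation of the arguments and flips when two
#' arguments are swapped.
#'
#' @param p1,p2,p3 numeric length-3 points (mm).
#' @return a [plane()] whose base point is `p1`.
#' @examples
#' pl <- plane_from_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' pl$normal  # (0, 0, 1)
#' @export
plane_from_points <- function(p1, p2, p3) {
  p1 <- vec3(p1); p2 <- vec3(p2); p3 <- vec3(p3)
  scale <- max(vnorm(p2 - p1), vnorm(p3 - p1), vnorm(p3 - p2))
  n <- cross3(p2 - p1, p3 - p1)
  if (scale == 0 || vnorm(n) <= 1e-8 * scale^2)
    stop(sprintf(
      "degenerate input: points (%s), (%s), (%s) are collinear or coincident",
      paste(signif(p1, 6), collapse = ", "),
      paste(signif(p2, 6), collapse = ", "),
      paste(signif(p3, 6), collapse = ", ")), call. = FALSE)
  plane(p1, n)
}

#' Least-squares sphere fit
#'
#' Fits a sphere to a point cloud: an algebraic (linear) fit provides the
#' initial estimate, which is then refined by Gauss-Newton iteration on the
#' orthogonal (geometric) distances `|p - c| - r`.  The algebraic stage
#' solves the linear system `2 p . c + (r^2 - |c|^2) = |p|^2` by least
#' squares; the geometric stage is the default reported fit.
#'
#' @param points >= 4 non-coplanar points (matrix or list).
#' @param method `"geometric"` (orthogonal-distance refinement, default) or
#'   `"algebraic"` (linear fit only).
#' @param max_iter,tol refinement controls: iteration cap and convergence
#'   tolerance on the parameter-change norm.
#' @return a [sphere()] with extra fields `rms` (root-mean-square orthogonal
#'   residual, mm) and `iterations`.
#' @export
fit_sphere <- function(points, method = c("geometric", "algebraic"),
                       max_iter = 100L, tol = 1e-10) {
  method <- match.arg(method)
  m <- as_point_matrix(points)
  n <- nrow(m)
  if (n < 4L) stop("degenerate input: sphere fitting needs at least 4 points", call. = FALSE)
  ctr <- colMeans(m)
  sv <- svd(sweep(m, 2L, ctr), nu = 0L)$d
  scale <- max(sv[1L], 1)
  if (sv[3L] <= 1e-8 * scale)
    stop("degenerate input: points are (near-)coplanar; sphere is not identifiable",
         call. = FALSE)

  # algebraic stage: 2 p.c + k = |p|^2 with k = r^2 - |c|^2
  A <- cbind(2 * m, 1)
  b <- rowSums(m * m)
  sol <- qr.solve(A, b)
  center <- sol[1:3]
  r2 <- sol[4L] + sum(center^2)
  if (r2 <= 0) stop("algebraic sphere fit produced a non-positive radius", call. = FALSE)
  radius <- sqrt(r2)
  iters <- 0L

  if (method == "geometric") {
    par <- c(center, radius)
    for (i in seq_len(max_iter)) {
      d <- m - matrix(par[1:3], n, 3L, byrow = TRUE)
      dist <- sqrt(rowSums(d * d))
      dist[dist < 1e-12] <- 1e-12
      resid <- dist - par[4L]
      # Jacobian of resid wrt (cx, cy, cz, r)
      J <- cbind(-d / dist, -1)
      step <- tryCatch(qr.solve(J, -resid), error = function(e) rep(0, 4))
      par <- par + step
      iters <- i
      if (vnorm(c(step)) < tol * (1 + vnorm(par))) break
    }
    center <- par[1:3]
    radius <- par[4L]
    if (!is.finite(radius) || radius <= 0)
      stop("geometric sphere refinement diverged", call. = FALSE)
  }

  d <- m - matrix(center, n, 3L, byrow = TRUE)
  rms <- sqrt(mean((sqrt(rowSums(d * d)) - radius)^2))
  out <- sphere(center, radius)
  out$rms <- rms
  out$iterations <- iters
  out$method <- method
  out
}

#' Least-squares cylinder-axis fit
#'
#' Estimates the central axis of an elongated point cloud (e.g. the femoral
#' diaphysis).  The initial axis is the first principal component through
#' the centroid; it is then refined by minimizing the variance of the radial
#' distances to the axis over axis direction and transverse offset.  The
#' direction sign is deterministic: positive dot product with +z, ties
#' broken toward +x then +y; when `proximal_hint` is given the sign is
#' chosen to point toward it (distal-to-proximal).
#'
#' @param points >= 6 points with dominant elongation (first principal
#'   extent at least twice the second).
#' @param proximal_hint optional point; the returned direction points from
#'   the centroid toward the side of the hint.
#' @return a [line3()] through the fitted axis with extra fields
#'   `radius` (mean radial distance, mm) and `radial_sd`.
#' @export
fit_axis <- function(points, proximal_hint = NULL) {
  m <- as_point_matrix(points)
  n <- nrow(m)
  if (n < 6L) stop("axis fitting needs at least 6 points", call. = FALSE)
  ctr <- colMeans(m)
  mc <- sweep(m, 2L, ctr)
  sv <- svd(mc, nu = 0L)
  if (sv$d[1L] < 2 * sv$d[2L])
    stop(sprintf(
      "low anisotropy: principal extent ratio %.2f < 2; point cloud is not elongated",
      sv$d[1L] / max(sv$d[2L], 1e-12)), call. = FALSE)
  dir0 <- sv$v[, 1L]

  # refine: minimize variance of radial distances over (theta, phi, o1, o2)
  basis_for <- function(d) {
    seed <- if (abs(d[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- unitize(cross3(d, seed))
    list(u = u, v = cross3(d, u))
  }
  sph <- c(acos(max(-1, min(1, dir0[3L]))), atan2(dir0[2L], dir0[1L]))
  obj <- function(p) {
    d <- c(sin(p[1L]) * cos(p[2L]), sin(p[1L]) * sin(p[2L]), cos(p[1L]))
    bb <- basis_for(d)
    o <- ctr + p[3L] * bb$u + p[4L] * bb$v
    rel <- m - matrix(o, n, 3L, byrow = TRUE)
    along <- drop(rel %*% d)
    rad2 <- rowSums(rel * rel) - along^2
    r <- sqrt(pmax(rad2, 0))
    stats::var(r)
  }
  opt <- stats::optim(c(sph, 0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 500L, reltol = 1e-14))
  p <- opt$par
  d <- c(sin(p[1L]) * cos(p[2L]), sin(p[1L]) * sin(p[2L]), cos(p[1L]))
  bb <- basis_for(d)
  o <- ctr + p[3L] * bb$u + p[4L] * bb$v

  if (!is.null(proximal_hint)) {
    if (sum((vec3(proximal_hint) - o) * d) < 0) d <- -d
  } else {
    s <- sign(d[3L])
    if (s == 0) s <- sign(d[1L])
    if (s == 0) s <- sign(d[2L])
    if (s < 0) d <- -d
  }
  rel <- m - matrix(o, n, 3L, byrow = TRUE)
  along <- drop(rel %*% d)
  r <- sqrt(pmax(rowSums(rel * rel) - along^2, 0))
  out <- line3(o, d)
  out$radius <- mean(r)
  out$radial_sd <- stats::sd(r)
  out
}

#' Closest approach of two 3D lines
#'
#' Returns the pair of mutually closest points on two (generically skew)
#' lines and their distance.  Used to realize axis "intersections" for axes
#' that do not exactly meet in 3D.
#'
#' @param a,b [line3()] objects with non-parallel directions.
#' @return list with `point_a`, `point_b` (mm), `distance` (mm), and
#'   `midpoint` (the symmetric intersection surrogate).
#' @export
closest_approach <- function(a, b) {
  stopifnot(inherits(a, "line3"), inherits(b, "line3"))
  da <- a$direction; db <- b$direction
  cr <- cross3(da, db)
  if (vnorm(cr) <= 1e-9)
    stop("parallel lines: closest approach is not unique", call. = FALSE)
  w <- b$point - a$point
  # solve [da.da  -da.db; da.db  -db.db] (s, t)' = (da.w, db.w)'
  A <- matrix(c(sum(da * da), -sum(da * db),
                sum(da * db), -sum(db * db)), 2L, 2L, byrow = TRUE)
  st <- solve(A, c(sum(da * w), sum(db * w)))
  pa <- a$point + st[1L] * da
  pb <- b$point + st[2L] * db
  list(point_a = pa, point_b = pb,
       distance = vnorm(pb - pa),
       midpoint = (pa + pb) / 2)
}

#' Signed projected angle between two vectors in a plane
#'
#' Projects `v` and `ref` onto the plane with unit normal `plane_normal`
#' and returns the signed angle from `ref` to `v`, in degrees, in
#' (-180, 180], with the sign given by the right-hand rule about the
#' normal.  This is the workhorse for frontal-plane (inclination) and
#' transverse-plane (version) angle measurements.
#'
#' @param v,ref numeric length-3 vectors.
#' @param plane_normal unit normal of the measurement plane.
#' @return signed angle in degrees.
#' @export
projected_angle <- function(v, ref, plane_normal) {
  nrm <- unitize(vec3(plane_normal))
  proj <- function(x) {
    x <- vec3(x)
    p <- x - sum(x * nrm) * nrm
    if (vnorm(p) <= 1e-9)
      stop("undefined projection: vector is (near-)parallel to the plane normal",
           call. = FALSE)
    p
  }
  vp <- proj(v); rp <- proj(ref)
  ang <- atan2(sum(cross3(rp, vp) * nrm), sum(rp * vp)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Rigid transform container and application
#'
#' A proper rigid transform (rotation + translation, no scaling or
#' reflection).  `apply_transform()` maps points; methods exist for point
#' matrices, [plane()], [line3()] and meshes.
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation numeric length-3 (mm).
#' @return object of class `"rigid_transform"`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  stopifnot(all(dim(rotation) == c(3L, 3L)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation matrix is not orthogonal", call. = FALSE)
  if (det(rotation) < 0)
    stop("rotation matrix is a reflection (det < 0)", call. = FALSE)
  structure(list(rotation = rotation, translation = vec3(translation)),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param transform a [rigid_transform()].
#' @param x points (n x 3 matrix or length-3 vector), [plane()], [line3()],
#'   or `bone_mesh`.
#' @export
apply_transform <- function(transform, x) UseMethod("apply_transform", x)

#' @export
apply_transform.default <- function(transform, x) {
  m <- as_point_matrix(x)
  out <- m %*% t(transform$rotation) +
    matrix(transform$translation, nrow(m), 3L, byrow = TRUE)
  if (!is.matrix(x) && length(x) == 3L) drop(out) else out
}

#' @export
apply_transform.plane <- function(transform, x) {
  plane(drop(transform$rotation %*% x$point) + transform$translation,
        drop(transform$rotation %*% x$normal))
}

#' @export
apply_transform.line3 <- function(transform, x) {
  line3(drop(transform$rotation %*% x$point) + transform$translation,
        drop(transform$rotation %*% x$direction))
}

#' @rdname rigid_transform
#' @param axis rotation axis (length-3); `angle_deg` rotation angle.
#' @param angle_deg rotation angle in degrees.
#' @export
rotation_about <- function(axis, angle_deg) {
  u <- unitize(vec3(axis))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3L], u[2L], u[3L], 0, -u[1L], -u[2L], u[1L], 0),
              3L, 3L, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Reflection of geometry across a plane
#'
#' Householder reflection across an arbitrary plane; the mirror operation
#' used to turn one side's surgical plan into contralateral targets.
#'
#' @param pl a [plane()].
#' @param x points, [plane()], [line3()] or mesh to reflect.
#' @return reflected object of the same type.
#' @export
reflect_across <- function(pl, x) UseMethod("reflect_across", x)

reflect_points <- function(pl, m) {
  d <- plane_distance(pl, m)
  m - 2 * outer(d, pl$normal)
}

#' @export
reflect_across.default <- function(pl, x) {
  m <- as_point_matrix(x)
  out <- reflect_points(pl, m)
  if (!is.matrix(x) && length(x) == 3L) drop(out) else out
}

#' @export
reflect_across.plane <- function(pl, x) {
  p <- drop(reflect_points(pl, matrix(x$point, 1L)))
  n <- x$normal - 2 * sum(x$normal * pl$normal) * pl$normal
  plane(p, n)
}

#' @export
reflect_across.line3 <- function(pl, x) {
  p <- drop(reflect_points(pl, matrix(x$point, 1L)))
  d <- x$direction - 2 * sum(x$direction * pl$normal) * pl$normal
  line3(p, d)
}
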