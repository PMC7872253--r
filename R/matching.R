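# Donor-recipient pairing by acetabular diameter, mirror-plan creation,
# deviation-from-plan records, and the paired one-tailed comparison.

#' Pair donors with recipients by acetabular diameter
#'
#' One-to-one assignment under the compatibility rule that the donor
#' acetabulum is 1-4 mm smaller than the recipient acetabulum.  Among
#' assignments with the maximum number of matched pairs, the one minimizing
#' the total deviation of the size differences from the window centre
#' (2.5 mm) is returned — a reproducible objective standing in for pairing
#' by eye.  Solved exactly by dynamic programming over donor subsets.
#'
#' @param recipient_diameters,donor_diameters named numeric vectors of mean
#'   acetabular diameters (mm).
#' @param window inclusive compatibility window for recipient - donor, mm.
#' @return data.frame of class `"match_table"` with columns `recipient_id`,
#'   `donor_id`, `recipient_diameter`, `donor_diameter`, `size_difference`;
#'   unmatched ids are in attributes `unmatched_recipients` /
#'   `unmatched_donors`.
#' @export
pair_donors <- function(recipient_diameters, donor_diameters,
                        window = c(1, 4)) {
  r <- recipient_diameters; d <- donor_diameters
  if (!length(r) || !length(d)) stop("diameter maps must be non-empty", call. = FALSE)
  if (is.null(names(r))) names(r) <- paste0("R", seq_along(r))
  if (is.null(names(d))) names(d) <- paste0("D", seq_along(d))
  nd <- length(d)
  if (nd > 16L)
    stop("exact assignment supported up to 16 donors", call. = FALSE)
  target <- mean(window)
  feas <- outer(r, d, "-")
  ok <- feas >= window[1L] & feas <= window[2L]
  cost <- abs(feas - target)

  # DP over recipients with a donor-subset bitmask; value = (matches, -cost)
  nmask <- bitwShiftL(1L, nd)
  INF <- 1e18
  best_m <- matrix(0L, length(r) + 1L, nmask)
  best_c <- matrix(0, length(r) + 1L, nmask)
  choice <- matrix(0L, length(r) + 1L, nmask)  # 0 = skip, j = donor used
  for (i in seq_along(r)) {
    for (mask in 0:(nmask - 1L)) {
      m0 <- best_m[i, mask + 1L]; c0 <- best_c[i, mask + 1L]; ch <- 0L
      for (j in seq_len(nd)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) == 0L || !ok[i, j]) next
        pm <- best_m[i, mask - bit + 1L] + 1L
        pc <- best_c[i, mask - bit + 1L] + cost[i, j]
        if (pm > m0 || (pm == m0 && pc < c0 - 1e-12)) { m0 <- pm; c0 <- pc; ch <- j }
      }
      best_m[i + 1L, mask + 1L] <- m0
      best_c[i + 1L, mask + 1L] <- c0
      choice[i + 1L, mask + 1L] <- ch
    }
  }
  # backtrack from the full donor set
  mask <- nmask - 1L
  rows <- list()
  for (i in rev(seq_along(r))) {
    j <- choice[i + 1L, mask + 1L]
    if (j > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        recipient_id = names(r)[i], donor_id = names(d)[j],
        recipient_diameter = unname(r[i]), donor_diameter = unname(d[j]),
        size_difference = unname(r[i] - d[j]), stringsAsFactors = FALSE)
      mask <- mask - bitwShiftL(1L, j - 1L)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rev(rows)) else
    data.frame(recipient_id = character(0), donor_id = character(0),
               recipient_diameter = numeric(0), donor_diameter = numeric(0),
               size_difference = numeric(0), stringsAsFactors = FALSE)
  class(tab) <- c("match_table", "data.frame")
  attr(tab, "unmatched_recipients") <- setdiff(names(r), tab$recipient_id)
  attr(tab, "unmatched_donors") <- setdiff(names(d), tab$donor_id)
  tab
}

#' Mirror a surgical plan or measurement to the contralateral side
#'
#' Reflects the geometry across a sagittal plane and flips the side flag,
#' producing target parameters for the contralateral hip.  Scalar targets —
#' inclination, neck length, and version under the side-aware anteversion-
#' positive convention — are preserved by construction.
#'
#' @param x an `osteotomy_plan`, `morphometry_result`, or [landmark_set()].
#' @param sagittal_plane a [plane()]; the mirror plane.
#' @return object of the same class, mirrored, with `side` flipped.
#' @export
mirror_plan <- function(x, sagittal_plane) UseMethod("mirror_plan")

flip_side <- function(side) if (identical(side, "right")) "left" else "right"

#' @export
mirror_plan.landmark_set <- function(x, sagittal_plane) {
  rp <- function(p) if (is.null(p)) NULL else drop(reflect_across(sagittal_plane, p))
  x$craniomedial <- rp(x$craniomedial); x$craniolateral <- rp(x$craniolateral)
  x$caudomedial <- rp(x$caudomedial); x$caudolateral <- rp(x$caudolateral)
  x$condyle_medial <- rp(x$condyle_medial); x$condyle_lateral <- rp(x$condyle_lateral)
  if (!is.null(x$acetabular))
    x$acetabular <- lapply(x$acetabular, function(s) lapply(s, rp))
  x$side <- flip_side(x$side)
  x
}

#' @export
mirror_plan.osteotomy_plan <- function(x, sagittal_plane) {
  structure(list(
    plane_a = reflect_across(sagittal_plane, x$plane_a),
    plane_b = reflect_across(sagittal_plane, x$plane_b),
    ridge = reflect_across(sagittal_plane, x$ridge),
    dihedral_angle = x$dihedral_angle,
    landmarks = mirror_plan(x$landmarks, sagittal_plane)),
    class = "osteotomy_plan")
}

#' @export
mirror_plan.morphometry_result <- function(x, sagittal_plane) {
  rf <- x$frame
  frame <- structure(list(
    origin = drop(reflect_across(sagittal_plane, rf$origin)),
    axis_prox = rf$axis_prox - 2 * sum(rf$axis_prox * sagittal_plane$normal) *
      sagittal_plane$normal,
    axis_ml = rf$axis_ml - 2 * sum(rf$axis_ml * sagittal_plane$normal) *
      sagittal_plane$normal,
    axis_cc = rf$axis_cc - 2 * sum(rf$axis_cc * sagittal_plane$normal) *
      sagittal_plane$normal,
    side = flip_side(rf$side)), class = "femoral_frame")
  structure(list(
    head_center = drop(reflect_across(sagittal_plane, x$head_center)),
    head_radius = x$head_radius, head_rms = x$head_rms,
    neck_axis = reflect_across(sagittal_plane, x$neck_axis),
    diaphyseal_axis = reflect_across(sagittal_plane, x$diaphyseal_axis),
    frame = frame,
    inclination = x$inclination, version = x$version,
    neck_length = x$neck_length,
    side = flip_side(x$side)), class = "morphometry_result")
}

#' Absolute deviation of a measurement from its plan
#'
#' @param measured,planned `morphometry_result` objects for the same
#'   subject and side (mirror the plan first when comparing across sides).
#' @param subject_id,group identifiers carried into the record.
#' @return one-row data.frame of class `"deviation_record"`: `subject_id`,
#'   `group`, `abs_dev_version` (deg), `abs_dev_inclination` (deg),
#'   `abs_dev_neck_length` (mm).
#' @export
deviation_from_plan <- function(measured, planned, subject_id = NA_character_,
                                group = NA_character_) {
  if (!identical(measured$side, planned$side))
    stop(sprintf("side mismatch: measured %s vs planned %s (mirror the plan first)",
                 measured$side, planned$side), call. = FALSE)
  out <- data.frame(
    subject_id = subject_id, group = group,
    abs_dev_version = abs(measured$version - planned$version),
    abs_dev_inclination = abs(measured$inclination - planned$inclination),
    abs_dev_neck_length = abs(measured$neck_length - planned$neck_length),
    stringsAsFactors = FALSE)
  class(out) <- c("deviation_record", "data.frame")
  out
}

#' Paired one-tailed t-test with normality check
#'
#' Compares paired samples with a one-tailed paired t-test at alpha = 0.05,
#' reporting the Shapiro-Wilk normality p-value of the paired differences
#' (the quantity entering the t statistic).  The direction of the
#' alternative must be stated by the caller.
#'
#' @param group_a,group_b equal-length numeric vectors (n >= 3), paired by
#'   index.
#' @param direction `"a_less"` (alternative: mean(a - b) < 0) or
#'   `"a_greater"`.
#' @param alpha significance level (default 0.05).
#' @return list of class `"paired_test_result"`: `n_pairs`, `mean_a`,
#'   `mean_b`, `sd_a`, `sd_b`, `t_statistic`, `p_one_tailed`, `shapiro_p`,
#'   `significant`, `alpha`, `direction`.
#' @export
paired_one_tailed_t <- function(group_a, group_b,
                                direction = c("a_less", "a_greater"),
                                alpha = 0.05) {
  direction <- match.arg(direction)
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) != length(b) || length(a) < 3L)
    stop("paired test needs equal-length samples with n >= 3", call. = FALSE)
  d <- a - b
  if (stats::sd(d) < 1e-12)
    stop("degenerate input: paired differences have zero variance", call. = FALSE)
  tt <- stats::t.test(a, b, paired = TRUE,
                      alternative = if (direction == "a_less") "less" else "greater")
  sw <- stats::shapiro.test(d)
  structure(list(
    n_pairs = length(a), mean_a = mean(a), mean_b = mean(b),
    sd_a = stats::sd(a), sd_b = stats::sd(b),
    t_statistic = unname(tt$statistic), p_one_tailed = tt$p.value,
    shapiro_p = sw$p.value, significant = tt$p.value < alpha,
    alpha = alpha, direction = direction), class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<paired one-tailed t-test (%s), n = %d pairs>\n",
    "  a: %.3f +/- %.3f   b: %.3f +/- %.3f\n",
    "  t = %.4f, p (one-tailed) = %.4g%s   [Shapiro-Wilk p = %.3f]\n"),
    x$direction, x$n_pairs, x$mean_a, x$sd_a, x$mean_b, x$sd_b,
    x$t_statistic, x$p_one_tailed, if (x$significant) " *" else "",
    x$shapiro_p))
  invisible(x)
}
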