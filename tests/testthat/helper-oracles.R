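# Independent oracles used to check the package's fitted quantities.
# These deliberately use different algorithms from the implementation
# (derivative-free multistart optimization, dense grid search, direct
# trigonometric identities).

# brute-force geometric least-squares sphere: multistart Nelder-Mead on the
# orthogonal-distance objective, no algebraic initialization
oracle_sphere_fit <- function(points) {
  m <- points
  obj <- function(par) {
    d <- sqrt(rowSums(sweep(m, 2L, par[1:3])^2))
    sum((d - par[4L])^2)
  }
  ctr <- colMeans(m)
  r0 <- mean(sqrt(rowSums(sweep(m, 2L, ctr)^2)))
  starts <- rbind(c(ctr, r0),
                  c(ctr + c(1, -1, 1), r0 * 1.2),
                  c(ctr + c(-2, 0.5, -1), r0 * 0.8),
                  c(ctr + c(0.5, 2, -0.5), r0 * 1.1))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(center = best$par[1:3], radius = best$par[4L])
}

# dense two-parameter grid search for the closest approach of two lines
oracle_closest_approach <- function(a, b, span = 60) {
  lo_s <- -span; hi_s <- span; lo_t <- -span; hi_t <- span
  for (round in 1:6) {
    s <- seq(lo_s, hi_s, length.out = 161L)
    t <- seq(lo_t, hi_t, length.out = 161L)
    pa <- outer(s, a$direction) + matrix(a$point, length(s), 3L, byrow = TRUE)
    pb <- outer(t, b$direction) + matrix(b$point, length(t), 3L, byrow = TRUE)
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
    ij <- arrayInd(which.min(d2), dim(d2))
    bs <- s[ij[1L]]; bt <- t[ij[2L]]
    hw_s <- (hi_s - lo_s) / 160 * 4
    hw_t <- (hi_t - lo_t) / 160 * 4
    lo_s <- bs - hw_s; hi_s <- bs + hw_s
    lo_t <- bt - hw_t; hi_t <- bt + hw_t
  }
  pa <- a$point + bs * a$direction
  pb <- b$point + bt * b$direction
  list(point_a = pa, point_b = pb, distance = sqrt(sum((pa - pb)^2)))
}

# signed projected angle computed from an explicit in-plane basis
oracle_projected_angle <- function(v, ref, n) {
  n <- n / sqrt(sum(n^2))
  proj <- function(x) x - sum(x * n) * n
  rp <- proj(ref); vp <- proj(v)
  u1 <- rp / sqrt(sum(rp^2))
  u2 <- c(n[2L] * u1[3L] - n[3L] * u1[2L],
          n[3L] * u1[1L] - n[1L] * u1[3L],
          n[1L] * u1[2L] - n[2L] * u1[1L])
  atan2(sum(vp * u2), sum(vp * u1)) * 180 / pi
}

sample_sphere_points <- function(n, center, radius, sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rnorm(3 * n), ncol = 3L)
  m <- m / sqrt(rowSums(m^2)) * radius
  m <- sweep(m, 2L, center, "+")
  if (sd > 0) m <- m + matrix(stats::rnorm(3 * n, sd = sd), ncol = 3L)
  m
}

sample_cylinder_points <- function(n, radius = 8, half_len = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- stats::runif(n, 0, 2 * pi)
  cbind(radius * cos(th), radius * sin(th), stats::runif(n, -half_len, half_len))
}

# exhaustive donor-recipient assignment oracle over all donor injections
oracle_pairing <- function(r, d, window = c(1, 4)) {
  nr <- length(r); nd <- length(d)
  best <- list(matches = -1L, cost = Inf, assign = NULL)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  for (p in perms(seq_len(nd))) {
    used <- p[seq_len(min(nr, nd))]
    matches <- 0L; cost <- 0
    assign <- rep(NA_integer_, nr)
    for (i in seq_len(min(nr, nd))) {
      diff <- unname(r[i] - d[used[i]])
      if (diff >= window[1L] && diff <= window[2L]) {
        matches <- matches + 1L
        cost <- cost + abs(diff - mean(window))
        assign[i] <- used[i]
      }
    }
    if (matches > best$matches ||
        (matches == best$matches && cost < best$cost - 1e-12)) {
      best <- list(matches = matches, cost = cost, assign = assign)
    }
  }
  best
}

random_rigid_transform <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ax <- stats::rnorm(3)
  R <- rotation_about(ax, stats::runif(1, -180, 180))
  rigid_transform(R, stats::rnorm(3, sd = 20))
}
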