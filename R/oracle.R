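# Independent numerical-quadrature oracle for every one-electron integral:
# Becke-partitioned, atom-centered radial x spherical product grids in plain
# Cartesian space. This path shares no code with the Hermite/Boys and
# Gaussian-transform evaluators it checks.

# values of a contracted AO at a set of points (n x 3)
ao_value <- function(ao, pts) {
  dx <- pts[, 1] - ao$center[1]
  dy <- pts[, 2] - ao$center[2]
  dz <- pts[, 3] - ao$center[3]
  r2 <- dx * dx + dy * dy + dz * dz
  poly <- dx^ao$pows[1] * dy^ao$pows[2] * dz^ao$pows[3]
  val <- 0
  for (ip in seq_along(ao$exps)) {
    val <- val + ao$coefs[ip] * exp(-ao$exps[ip] * r2)
  }
  val * poly
}

# Laplacian of a contracted AO at a set of points (analytic, per primitive)
ao_laplacian <- function(ao, pts) {
  d <- lapply(1:3, function(k) pts[, k] - ao$center[k])
  r2 <- d[[1]]^2 + d[[2]]^2 + d[[3]]^2
  out <- numeric(nrow(pts))
  for (ip in seq_along(ao$exps)) {
    a <- ao$exps[ip]
    g <- exp(-a * r2)
    mono <- lapply(1:3, function(k) d[[k]]^ao$pows[k])
    term <- numeric(nrow(pts))
    for (k in 1:3) {
      i <- ao$pows[k]
      lap1 <- -2 * a * (2 * i + 1) * d[[k]]^i + 4 * a^2 * d[[k]]^(i + 2)
      if (i >= 2) lap1 <- lap1 + i * (i - 1) * d[[k]]^(i - 2)
      oth <- Reduce(`*`, mono[-k])
      term <- term + lap1 * oth
    }
    out <- out + ao$coefs[ip] * term * g
  }
  out
}

# one Becke-style molecular grid level
becke_grid <- function(centers, scales, n_rad, n_theta) {
  centers <- matrix(centers, ncol = 3)
  nc <- nrow(centers)
  glr <- gauss_legendre_cached(n_rad)
  x <- (glr$nodes + 1) / 2
  wx <- glr$weights / 2
  glt <- gauss_legendre_cached(n_theta)
  ct <- glt$nodes
  wt <- glt$weights
  n_phi <- 2 * n_theta
  phi <- 2 * pi * (seq_len(n_phi) - 0.5) / n_phi
  wphi <- 2 * pi / n_phi

  st <- sqrt(pmax(0, 1 - ct^2))
  ang <- cbind(rep(st, each = n_phi) * cos(rep(phi, times = n_theta)),
               rep(st, each = n_phi) * sin(rep(phi, times = n_theta)),
               rep(ct, each = n_phi))
  wang <- rep(wt, each = n_phi) * wphi

  pts_all <- vector("list", nc)
  w_all <- vector("list", nc)
  for (c in seq_len(nc)) {
    r <- scales[c] * x^2 / (1 - x)^2
    dr <- scales[c] * 2 * x / (1 - x)^3
    wr <- wx * dr * r^2
    npt <- length(r) * nrow(ang)
    pts <- matrix(0, npt, 3)
    w <- numeric(npt)
    idx <- 1
    for (ir in seq_along(r)) {
      rows <- idx:(idx + nrow(ang) - 1)
      pts[rows, ] <- sweep(ang * r[ir], 2, centers[c, ], "+")
      w[rows] <- wr[ir] * wang
      idx <- idx + nrow(ang)
    }
    pts_all[[c]] <- pts
    w_all[[c]] <- w
  }
  pts <- do.call(rbind, pts_all)
  w <- unlist(w_all)
  owner <- rep(seq_len(nc), vapply(w_all, length, 1L))

  if (nc > 1) {
    # Becke partition of unity (3 iterations of the smoothing polynomial)
    dmat <- sapply(seq_len(nc), function(c)
      sqrt(rowSums(sweep(pts, 2, centers[c, ], "-")^2)))
    P <- matrix(1, nrow(pts), nc)
    sfun <- function(mu) {
      for (it in 1:3) mu <- 1.5 * mu - 0.5 * mu^3
      0.5 * (1 - mu)
    }
    Rij <- as.matrix(stats::dist(centers))
    for (i in seq_len(nc)) for (j in seq_len(nc)) {
      if (i == j) next
      mu <- (dmat[, i] - dmat[, j]) / Rij[i, j]
      P[, i] <- P[, i] * sfun(mu)
    }
    wb <- P[cbind(seq_len(nrow(pts)), owner)] / rowSums(P)
    wb[!is.finite(wb)] <- 0
    w <- w * wb
  }
  list(points = pts, weights = w)
}

#' Adaptive 3-D quadrature oracle
#'
#' Integrates an arbitrary Gaussian-envelope integrand over all space on
#' Becke-partitioned atom-centered grids, escalating through three grid
#' levels until successive levels agree below `tol`. Used throughout the test
#' suite as the independent check on every analytic integral path.
#'
#' @param integrand Vectorized function taking an `n x 3` matrix of points
#'   and returning `n` values.
#' @param centers Matrix (m x 3) of grid centers (AO centers, sites, charge
#'   positions).
#' @param scales Radial scale per center (bohr); roughly the extent of the
#'   features around that center.
#' @param tol Absolute tolerance on the difference of successive levels.
#' @return List with `value` and `error` (the last inter-level difference).
#' @export
quadrature_oracle <- function(integrand, centers, scales = NULL, tol = 1e-9) {
  centers <- unique(round(matrix(centers, ncol = 3), 12))
  if (is.null(scales)) scales <- rep(1.0, nrow(centers))
  if (length(scales) == 1) scales <- rep(scales, nrow(centers))
  levels <- list(c(55, 14), c(85, 20), c(130, 28))
  prev <- NA_real_
  err <- Inf
  for (lv in levels) {
    g <- becke_grid(centers, scales, lv[1], lv[2])
    val <- sum(g$weights * integrand(g$points))
    if (!is.na(prev)) {
      err <- abs(val - prev)
      if (err < tol) return(list(value = val, error = err))
    }
    prev <- val
  }
  if (err > tol * 100) {
    stop(sprintf(paste0("quadrature oracle did not converge: last level ",
                        "(%d radial x %d theta) changed the value by %.3e ",
                        "(tol %.1e)"), levels[[3]][1], levels[[3]][2], err, tol))
  }
  list(value = val, error = err)
}

#' @rdname quadrature_oracle
#' @details `quadrature_oracle_multi` integrates a vector-valued integrand
#'   (function returning an `n x k` matrix) on shared grids, converging the
#'   worst component.
#' @export
quadrature_oracle_multi <- function(integrand, centers, scales = NULL,
                                    tol = 1e-9) {
  centers <- unique(round(matrix(centers, ncol = 3), 12))
  if (is.null(scales)) scales <- rep(1.0, nrow(centers))
  if (length(scales) == 1) scales <- rep(scales, nrow(centers))
  levels <- list(c(55, 14), c(85, 20), c(130, 28))
  prev <- NULL
  err <- Inf
  for (lv in levels) {
    g <- becke_grid(centers, scales, lv[1], lv[2])
    val <- colSums(g$weights * integrand(g$points))
    if (!is.null(prev)) {
      err <- max(abs(val - prev))
      if (err < tol) return(list(value = val, error = err))
    }
    prev <- val
  }
  if (err > tol * 100) {
    stop(sprintf("quadrature oracle did not converge (last change %.3e)", err))
  }
  list(value = val, error = err)
}

# all 3 field components (and optionally the 6 CPP components) on one grid
oracle_field_multi <- function(ao1, ao2, R, r0, tol = 1e-9) {
  quadrature_oracle_multi(function(p) {
    d <- sweep(p, 2, R, "-")
    r <- sqrt(rowSums(d * d))
    w <- ao_value(ao1, p) * ao_value(ao2, p) *
      field_damping(r, r0) / pmax(r, 1e-300)^3
    d * w
  }, rbind(ao1$center, ao2$center, R),
  ao_scale(ao1, ao2, extra = max(r0, 0.5)), tol)$value
}

oracle_cpp_multi <- function(ao1, ao2, R, r0, tol = 1e-9) {
  comps <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  v <- quadrature_oracle_multi(function(p) {
    d <- sweep(p, 2, R, "-")
    r <- sqrt(rowSums(d * d))
    w <- ao_value(ao1, p) * ao_value(ao2, p) *
      field_damping(r, r0)^2 / pmax(r, 1e-300)^6
    cbind(d[, 1]^2, d[, 2]^2, d[, 3]^2,
          d[, 1] * d[, 2], d[, 1] * d[, 3], d[, 2] * d[, 3]) * w
  }, rbind(ao1$center, ao2$center, R),
  ao_scale(ao1, ao2, extra = max(r0, 0.5)), tol)$value
  out <- matrix(0, 3, 3)
  out[cbind(comps[, 1], comps[, 2])] <- v
  out[cbind(comps[, 2], comps[, 1])] <- v
  out
}

# ---- convenience integrand builders used by the tests ----------------------

oracle_overlap <- function(ao1, ao2, tol = 1e-9) {
  quadrature_oracle(function(p) ao_value(ao1, p) * ao_value(ao2, p),
                    rbind(ao1$center, ao2$center),
                    ao_scale(ao1, ao2), tol)$value
}

oracle_kinetic <- function(ao1, ao2, tol = 1e-9) {
  quadrature_oracle(function(p) -0.5 * ao_value(ao1, p) * ao_laplacian(ao2, p),
                    rbind(ao1$center, ao2$center),
                    ao_scale(ao1, ao2), tol)$value
}

oracle_nuc <- function(ao1, ao2, C, tol = 1e-9) {
  quadrature_oracle(function(p) {
    r <- sqrt(rowSums(sweep(p, 2, C, "-")^2))
    ao_value(ao1, p) * ao_value(ao2, p) / pmax(r, 1e-300)
  }, rbind(ao1$center, ao2$center, C), ao_scale(ao1, ao2, extra = 1), tol)$value
}

oracle_field <- function(ao1, ao2, R, r0, tol = 1e-9) {
  vapply(1:3, function(alpha) {
    quadrature_oracle(function(p) {
      d <- sweep(p, 2, R, "-")
      r <- sqrt(rowSums(d * d))
      ao_value(ao1, p) * ao_value(ao2, p) *
        field_damping(r, r0) * d[, alpha] / pmax(r, 1e-300)^3
    }, rbind(ao1$center, ao2$center, R),
    ao_scale(ao1, ao2, extra = max(r0, 0.5)), tol)$value
  }, 1.0)
}

oracle_cpp <- function(ao1, ao2, R, r0, tol = 1e-9) {
  out <- matrix(0, 3, 3)
  for (alpha in 1:3) for (beta in alpha:3) {
    out[alpha, beta] <- out[beta, alpha] <-
      quadrature_oracle(function(p) {
        d <- sweep(p, 2, R, "-")
        r <- sqrt(rowSums(d * d))
        ao_value(ao1, p) * ao_value(ao2, p) *
          field_damping(r, r0)^2 * d[, alpha] * d[, beta] / pmax(r, 1e-300)^6
      }, rbind(ao1$center, ao2$center, R),
      ao_scale(ao1, ao2, extra = max(r0, 0.5)), tol)$value
  }
  out
}

# radial scales: softest primitive dominates the extent around each center
ao_scale <- function(ao1, ao2, extra = NULL) {
  s <- c(1 / sqrt(min(ao1$exps)), 1 / sqrt(min(ao2$exps)))
  if (!is.null(extra)) s <- c(s, extra)
  pmax(pmin(s, 3), 0.3)
}
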