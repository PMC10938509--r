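# Shared-table ERI engine: one Hermite-Coulomb table per primitive quartet
# serves the integral value and all center derivatives. The derivative with
# respect to a center collapses into a single contraction by replacing the
# one-dimensional Hermite expansion coefficients with
#   dE(dim) = 2a E(i+1, j) - i E(i-1, j)
# so a quartet with derivatives costs 10 small contractions instead of 19
# Boys-table evaluations. Used by electron_repulsion() and the gradient
# accumulator; cross-checked against the independent per-quartet path
# (ao_quartet_eri) in the tests.

.eri_idx_cache <- new.env(parent = emptyenv())

expand_idx0 <- function(n) {
  cbind(rep(0:(n[1] - 1), times = n[2] * n[3]),
        rep(rep(0:(n[2] - 1), each = n[1]), times = n[3]),
        rep(0:(n[3] - 1), each = n[1] * n[2]))
}

eri_idx <- function(nb, nk, L1) {
  key <- as.character(nb[1] + 8 * (nb[2] + 8 * (nb[3] + 8 * (nk[1] + 8 *
         (nk[2] + 8 * (nk[3] + 8 * L1))))))
  v <- .eri_idx_cache[[key]]
  if (!is.null(v)) return(v)
  bt <- expand_idx0(nb)
  kt <- expand_idx0(nk)
  idx <- matrix(0L, nrow(bt), nrow(kt))
  for (k in seq_len(nrow(kt))) {
    idx[, k] <- 1L + (bt[, 1] + kt[k, 1]) + (bt[, 2] + kt[k, 2]) * L1 +
      (bt[, 3] + kt[k, 3]) * L1 * L1
  }
  sgn <- (-1)^rowSums(kt)
  v <- list(idx = idx, sgn = sgn)
  .eri_idx_cache[[key]] <- v
  v
}

# per contracted pair: primitive-pair data with Hermite coefficients and,
# optionally, the combined derivative coefficients per slot and dimension
eri_pair_data <- function(ao1, ao2, deriv = FALSE) {
  n1 <- length(ao1$exps); n2 <- length(ao2$exps)
  la <- ao1$pows; lb <- ao2$pows
  A <- ao1$center; B <- ao2$center
  out <- vector("list", n1 * n2)
  k <- 1
  for (ip in seq_len(n1)) for (jp in seq_len(n2)) {
    a <- ao1$exps[ip]; b <- ao2$exps[jp]
    p <- a + b
    P <- (a * A + b * B) / p
    E <- vector("list", 3)
    dE1 <- dE2 <- vector("list", 3)
    for (d in 1:3) {
      i <- la[d]; j <- lb[d]; AB <- A[d] - B[d]
      base <- ecoeffs(i, j, a, b, AB)
      E[[d]] <- base
      if (deriv) {
        ep <- ecoeffs(i + 1, j, a, b, AB)
        v <- 2 * a * ep
        if (i > 0) {
          em <- ecoeffs(i - 1, j, a, b, AB)
          v <- v - i * c(em, 0, 0)
        }
        dE1[[d]] <- v
        ep2 <- ecoeffs(i, j + 1, a, b, AB)
        v2 <- 2 * b * ep2
        if (j > 0) {
          em2 <- ecoeffs(i, j - 1, a, b, AB)
          v2 <- v2 - j * c(em2, 0, 0)
        }
        dE2[[d]] <- v2
      }
    }
    out[[k]] <- list(p = p, P = P, coef = ao1$coefs[ip] * ao2$coefs[jp],
                     E = E, dE1 = dE1, dE2 = dE2)
    k <- k + 1
  }
  out
}

ebra3 <- function(Ex, Ey, Ez) {
  nx <- length(Ex); ny <- length(Ey); nz <- length(Ez)
  if (nx * ny * nz == 1L) return(Ex * Ey * Ez)
  xy <- rep.int(Ex, ny) * rep(Ey, each = nx)
  rep.int(xy, nz) * rep(Ez, each = nx * ny)
}

# value and (optionally) all 12 center-derivative components of one
# contracted quartet; returns list(value, deriv = 4 x 3 matrix)
eri_quartet_engine <- function(pd_bra, pd_ket, deriv = FALSE) {
  val <- 0
  dv <- if (deriv) matrix(0, 4, 3) else NULL
  for (pb in pd_bra) for (pk in pd_ket) {
    p <- pb$p; q <- pk$p
    omega <- p * q / (p + q)
    X <- pb$P - pk$P
    nb <- vapply(pb$E, length, 1L)
    nk <- vapply(pk$E, length, 1L)
    Lb <- sum(nb - 1); Lk <- sum(nk - 1)
    L <- Lb + Lk + if (deriv) 1L else 0L
    R0 <- hermite_coulomb(L, omega, X)
    R0 <- as.vector(R0)
    L1 <- L + 1L
    fac <- pb$coef * pk$coef * 2 * pi^2.5 / (p * q * sqrt(p + q))

    eb <- ebra3(pb$E[[1]], pb$E[[2]], pb$E[[3]])
    ek <- ebra3(pk$E[[1]], pk$E[[2]], pk$E[[3]])
    ix <- eri_idx(nb, nk, L1)
    M <- matrix(R0[ix$idx], length(eb), length(ek))
    kv <- M %*% (ek * ix$sgn)
    val <- val + fac * sum(eb * kv)

    if (deriv) {
      for (d in 1:3) {
        # slot 1: bra AO1 center
        Ev <- pb$E; Ev[[d]] <- pb$dE1[[d]]
        nbd <- nb; nbd[d] <- length(Ev[[d]])
        ixd <- eri_idx(nbd, nk, L1)
        Md <- matrix(R0[ixd$idx], prod(nbd), length(ek))
        dv[1, d] <- dv[1, d] +
          fac * sum(ebra3(Ev[[1]], Ev[[2]], Ev[[3]]) * (Md %*% (ek * ixd$sgn)))
        # slot 2: bra AO2 center
        Ev[[d]] <- pb$dE2[[d]]
        dv[2, d] <- dv[2, d] +
          fac * sum(ebra3(Ev[[1]], Ev[[2]], Ev[[3]]) * (Md %*% (ek * ixd$sgn)))
        # slot 3: ket AO1 center
        Ekv <- pk$E; Ekv[[d]] <- pk$dE1[[d]]
        nkd <- nk; nkd[d] <- length(Ekv[[d]])
        ixk <- eri_idx(nb, nkd, L1)
        Mk <- matrix(R0[ixk$idx], length(eb), prod(nkd))
        dv[3, d] <- dv[3, d] +
          fac * sum(eb * (Mk %*% (ebra3(Ekv[[1]], Ekv[[2]], Ekv[[3]]) * ixk$sgn)))
      }
    }
  }
  if (deriv) dv[4, ] <- -(dv[1, ] + dv[2, ] + dv[3, ])
  list(value = val, deriv = dv)
}
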