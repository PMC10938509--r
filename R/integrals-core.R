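# One- and two-electron integrals over contracted Cartesian Gaussians by the
# McMurchie-Davidson scheme: Hermite expansion coefficients E_t^{ij}, Hermite
# Coulomb integrals R_tuv built on the Boys function, and contracted
# overlap/kinetic/nuclear-attraction/electron-repulsion wrappers. Derivatives
# with respect to basis-function centers are obtained elsewhere by the
# angular-momentum raising/lowering identity, so every routine here accepts
# arbitrary (small) Cartesian powers even though user-facing bases are s/p.

# Hermite expansion coefficients for one Cartesian dimension:
# (x-A)^i (x-B)^j exp(-a(x-A)^2 - b(x-B)^2) = sum_t E_t Lambda_t(x; p, P)
# E includes the Gaussian product prefactor exp(-mu AB^2).
ecoeffs <- function(i, j, a, b, AB) {
  p <- a + b
  mu <- a * b / p
  # E[t+1, ii+1, jj+1]
  E <- array(0, dim = c(i + j + 1, i + 1, j + 1))
  E[1, 1, 1] <- exp(-mu * AB * AB)
  XPA <- -b * AB / p   # P - A with AB = A - B
  XPB <-  a * AB / p
  if (i + j == 0) return(E[, 1, 1])
  for (jj in 0:j) {
    for (ii in 0:i) {
      if (ii == 0 && jj == 0) next
      if (ii > 0) {
        src <- E[, ii, jj + 1]
        for (t in 0:(ii + jj)) {
          v <- XPA * src[t + 1]
          if (t > 0) v <- v + src[t] / (2 * p)
          if (t + 2 <= ii + jj) v <- v + (t + 1) * src[t + 2]
          E[t + 1, ii + 1, jj + 1] <- v
        }
      } else {
        src <- E[, 1, jj]
        for (t in 0:jj) {
          v <- XPB * src[t + 1]
          if (t > 0) v <- v + src[t] / (2 * p)
          if (t + 2 <= jj) v <- v + (t + 1) * src[t + 2]
          E[t + 1, 1, jj + 1] <- v
        }
      }
    }
  }
  E[, i + 1, j + 1]
}

# Hermite Coulomb integrals R^0_tuv(p, X) for all t+u+v <= L, as an array
# R[t+1, u+1, v+1]. R^n_000 = (-2p)^n F_n(p |X|^2). Flat-vector recursion:
# index(n, t, u, v) = n*s4 + t + u*s2 + v*s3 (0-based) for speed.
hermite_coulomb <- function(L, p, X) {
  Fb <- boys(L, p * sum(X * X))
  L1 <- L + 1L
  s2 <- L1; s3 <- L1 * L1; s4 <- L1^3
  R <- numeric(L1 * s4)
  R[(0:L) * s4 + 1] <- (-2 * p)^(0:L) * Fb
  if (L > 0) {
    for (ord in 1:L) {
      nns <- 0:(L - ord)
      for (t in 0:ord) for (u in 0:(ord - t)) {
        v <- ord - t - u
        base <- t + u * s2 + v * s3
        if (t > 0) {
          val <- X[1] * R[(nns + 1) * s4 + (base - 1) + 1]
          if (t > 1) val <- val + (t - 1) * R[(nns + 1) * s4 + (base - 2) + 1]
        } else if (u > 0) {
          val <- X[2] * R[(nns + 1) * s4 + (base - s2) + 1]
          if (u > 1) val <- val + (u - 1) * R[(nns + 1) * s4 + (base - 2 * s2) + 1]
        } else {
          val <- X[3] * R[(nns + 1) * s4 + (base - s3) + 1]
          if (v > 1) val <- val + (v - 1) * R[(nns + 1) * s4 + (base - 2 * s3) + 1]
        }
        R[nns * s4 + base + 1] <- val
      }
    }
  }
  array(R[seq_len(s4)], dim = c(L1, L1, L1))
}

# ---- primitive integrals ---------------------------------------------------

prim_overlap_1d <- function(i, j, a, b, AB) {
  ecoeffs(i, j, a, b, AB)[1] * sqrt(pi / (a + b))
}

prim_overlap <- function(a, A, la, b, B, lb) {
  prod(vapply(1:3, function(d) prim_overlap_1d(la[d], lb[d], a, b, A[d] - B[d]),
              1.0))
}

# kinetic energy: 1D composition -1/2 d^2/dx^2 acting on the ket
prim_kinetic <- function(a, A, la, b, B, lb) {
  s <- vapply(1:3, function(d) prim_overlap_1d(la[d], lb[d], a, b, A[d] - B[d]),
              1.0)
  k1 <- function(d) {
    i <- la[d]; j <- lb[d]; AB <- A[d] - B[d]
    t <- 4 * b * b * prim_overlap_1d(i, j + 2, a, b, AB) -
      2 * b * (2 * j + 1) * prim_overlap_1d(i, j, a, b, AB)
    if (j >= 2) t <- t + j * (j - 1) * prim_overlap_1d(i, j - 2, a, b, AB)
    -0.5 * t
  }
  k1(1) * s[2] * s[3] + s[1] * k1(2) * s[3] + s[1] * s[2] * k1(3)
}

# <g_a | 1/|r - C| | g_b>  (unit positive source at C; no charge sign)
prim_nuc <- function(a, A, la, b, B, lb, C) {
  p <- a + b
  P <- (a * A + b * B) / p
  L <- sum(la) + sum(lb)
  Ex <- ecoeffs(la[1], lb[1], a, b, A[1] - B[1])
  Ey <- ecoeffs(la[2], lb[2], a, b, A[2] - B[2])
  Ez <- ecoeffs(la[3], lb[3], a, b, A[3] - B[3])
  R0 <- hermite_coulomb(L, p, P - C)
  if (L == 0) R0 <- array(R0, dim = c(1, 1, 1))
  acc <- 0
  for (t in seq_along(Ex)) for (u in seq_along(Ey)) for (v in seq_along(Ez)) {
    acc <- acc + Ex[t] * Ey[u] * Ez[v] * R0[t, u, v]
  }
  2 * pi / p * acc
}

# electron repulsion (ab|cd) in chemists' notation over primitives
prim_eri <- function(a, A, la, b, B, lb, c, C, lc, d, D, ld) {
  p <- a + b
  q <- c + d
  P <- (a * A + b * B) / p
  Q <- (c * C + d * D) / q
  omega <- p * q / (p + q)
  L1 <- sum(la) + sum(lb)
  L2 <- sum(lc) + sum(ld)
  E1 <- lapply(1:3, function(dd) ecoeffs(la[dd], lb[dd], a, b, A[dd] - B[dd]))
  E2 <- lapply(1:3, function(dd) ecoeffs(lc[dd], ld[dd], c, d, C[dd] - D[dd]))
  R0 <- hermite_coulomb(L1 + L2, omega, P - Q)
  if (L1 + L2 == 0) R0 <- array(R0, dim = c(1, 1, 1))
  acc <- 0
  for (t in seq_along(E1[[1]])) for (u in seq_along(E1[[2]])) for (v in seq_along(E1[[3]])) {
    e1 <- E1[[1]][t] * E1[[2]][u] * E1[[3]][v]
    if (e1 == 0) next
    for (tt in seq_along(E2[[1]])) for (uu in seq_along(E2[[2]])) for (vv in seq_along(E2[[3]])) {
      e2 <- E2[[1]][tt] * E2[[2]][uu] * E2[[3]][vv]
      if (e2 == 0) next
      sgn <- if ((tt + uu + vv - 3) %% 2 == 0) 1 else -1
      acc <- acc + e1 * e2 * sgn * R0[t + tt - 1, u + uu - 1, v + vv - 1]
    }
  }
  2 * pi^2.5 / (p * q * sqrt(p + q)) * acc
}

# ---- contracted wrappers ---------------------------------------------------

contract_pair <- function(ao1, ao2, fn) {
  acc <- 0
  for (ip in seq_along(ao1$exps)) for (jp in seq_along(ao2$exps)) {
    acc <- acc + ao1$coefs[ip] * ao2$coefs[jp] *
      fn(ao1$exps[ip], ao1$center, ao1$pows,
         ao2$exps[jp], ao2$center, ao2$pows)
  }
  acc
}

ao_pair_overlap <- function(ao1, ao2) contract_pair(ao1, ao2, prim_overlap)
ao_pair_kinetic <- function(ao1, ao2) contract_pair(ao1, ao2, prim_kinetic)

ao_pair_nuc <- function(ao1, ao2, C) {
  contract_pair(ao1, ao2, function(a, A, la, b, B, lb)
    prim_nuc(a, A, la, b, B, lb, C))
}

ao_quartet_eri <- function(ao1, ao2, ao3, ao4) {
  acc <- 0
  for (ip in seq_along(ao1$exps)) for (jp in seq_along(ao2$exps)) {
    cij <- ao1$coefs[ip] * ao2$coefs[jp]
    for (kp in seq_along(ao3$exps)) for (lp in seq_along(ao4$exps)) {
      acc <- acc + cij * ao3$coefs[kp] * ao4$coefs[lp] *
        prim_eri(ao1$exps[ip], ao1$center, ao1$pows,
                 ao2$exps[jp], ao2$center, ao2$pows,
                 ao3$exps[kp], ao3$center, ao3$pows,
                 ao4$exps[lp], ao4$center, ao4$pows)
    }
  }
  acc
}

#' Overlap, kinetic and nuclear-attraction matrices
#'
#' Base SCF one-electron ingredients over a contracted AO basis. `V` is the
#' potential-energy matrix of an electron in the field of the positive point
#' charges supplied (QM nuclei and, if desired, MM charges):
#' \eqn{V_{\mu\nu} = -\sum_c q_c \langle\mu|1/|r - R_c||\nu\rangle}.
#'
#' @param basis An [build_basis()] result.
#' @param centers Matrix (n x 3) of charge positions (bohr); may have 0 rows.
#' @param charges Numeric vector of charges (positive for nuclei).
#' @return List with symmetric matrices `S`, `T`, `V` and, when the smallest
#'   eigenvalue of `S` falls below `1e-10`, a `linear_dependence` flag that
#'   routes downstream overlap inversions through the pseudoinverse.
#' @export
overlap_kinetic_nuclear <- function(basis, centers = NULL, charges = NULL) {
  n <- length(basis)
  S <- matrix(0, n, n)
  Tm <- matrix(0, n, n)
  V <- matrix(0, n, n)
  if (is.null(centers)) centers <- matrix(0, 0, 3)
  centers <- matrix(centers, ncol = 3)
  for (i in seq_len(n)) for (j in i:n) {
    S[i, j] <- S[j, i] <- ao_pair_overlap(basis[[i]], basis[[j]])
    Tm[i, j] <- Tm[j, i] <- ao_pair_kinetic(basis[[i]], basis[[j]])
    if (nrow(centers) > 0) {
      v <- 0
      for (c in seq_len(nrow(centers))) {
        v <- v - charges[c] * ao_pair_nuc(basis[[i]], basis[[j]], centers[c, ])
      }
      V[i, j] <- V[j, i] <- v
    }
  }
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  list(S = S, T = Tm, V = V, linear_dependence = ev_min < 1e-10)
}

#' Two-electron repulsion integrals
#'
#' Dense four-index tensor `(mu nu | lambda sigma)` in chemists' notation,
#' assembled with the full 8-fold permutational symmetry. Desk scale only;
#' refuses bases beyond `max_nao` functions.
#'
#' @param basis An [build_basis()] result.
#' @param max_nao Resource guard on the basis size.
#' @return Four-dimensional array of dimension `n^4`.
#' @export
electron_repulsion <- function(basis, max_nao = 24) {
  n <- length(basis)
  if (n > max_nao)
    stop("dense ERI storage refused for ", n, " AOs (guard: ", max_nao, ")")
  eri <- array(0, dim = rep(n, 4))
  pd <- vector("list", n * n)
  pget <- function(i, j) {
    key <- (i - 1) * n + j
    if (is.null(pd[[key]])) pd[[key]] <<- eri_pair_data(basis[[i]], basis[[j]])
    pd[[key]]
  }
  for (i in seq_len(n)) for (j in 1:i) for (k in 1:i) {
    lmax <- if (k == i) j else k
    for (l in 1:lmax) {
      v <- eri_quartet_engine(pget(i, j), pget(k, l))$value
      eri[i, j, k, l] <- eri[j, i, k, l] <- eri[i, j, l, k] <- eri[j, i, l, k] <- v
      eri[k, l, i, j] <- eri[l, k, i, j] <- eri[k, l, j, i] <- eri[l, k, j, i] <- v
    }
  }
  eri
}
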