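# Direct reaction field corrections to the electronic Hamiltonian: the
# zero-electron constant, the one-electron core-Hamiltonian correction
# (resolution-of-identity with optional exact same-site replacement), the
# precomputed density-independent intermediates AF and AF^(n), and the
# factorized Coulomb/exchange corrections with their explicit four-index
# oracle.
#
# Sign bookkeeping, fixed once for the whole package: F^(e) holds the field
# of the electron (charge included), F^(n) the fields of nuclei and MM
# charges, and the polarization energy operator is -1/2 f^T A f with
# f = sum_a f^(e)_a + f^(n). Grouping by electron count gives
#   two-electron:   (mu nu|la si)_pol = -F^(e)T_{mu nu} A F^(e)_{la si}
#   one-electron:   cross term -F^(n)T A F^(e) plus the same-electron
#                   self-interaction -1/2 <mu| f^(e)T A f^(e) |nu>
#   zero-electron:  -1/2 F^(n)T A F^(n)
# Every term is cross-checked by the energy-assembly and finite-difference
# oracles in the test suite.

# flatten (3Np, N, N) to (3Np, N^2); column-major over (mu, nu)
fe_as_matrix <- function(Fe) {
  d <- dim(Fe)
  dim(Fe) <- c(d[1], d[2] * d[3])
  Fe
}

#' Zero-electron direct reaction field constant
#'
#' \deqn{E^{(0)}_{pol} = -\tfrac12 F^{(n)T} A F^{(n)},}
#' added to the classical nuclear-nuclear repulsion. It contains the full MM
#' polarization energy (the response of the dipoles to nuclei and MM
#' charges), which must therefore never be added separately elsewhere.
#'
#' @param A Effective polarizability supermatrix.
#' @param Fn Damped field supervector from [nuclear_field_vectors()].
#' @return Scalar energy (hartree).
#' @export
zero_electron_term <- function(A, Fn) {
  if (length(Fn) == 0) return(0)
  -0.5 * sum(Fn * as.vector(A %*% Fn))
}

#' Precompute density-independent DRF intermediates
#'
#' `AF[i,mu,nu] = sum_j A_ij F^(e)_j,mu,nu` and `AFn = A F^(n)` depend only
#' on geometry and basis and are computed once per geometry; `S_inv` is the
#' inverse overlap for the resolution-of-identity, replaced by the
#' pseudoinverse (singular values below `threshold` times the largest
#' removed) when the basis is linearly dependent.
#'
#' @param Fe Field-integral array from [damped_field_integrals()].
#' @param Fn Field supervector from [nuclear_field_vectors()].
#' @param A Effective polarizability supermatrix.
#' @param S Overlap matrix.
#' @param threshold Relative singular-value cutoff for the pseudoinverse.
#' @return List with `AF` (same shape as `Fe`), `AFn`, `S_inv`, and
#'   `pseudoinverse` flag.
#' @export
build_intermediates <- function(Fe, Fn, A, S, threshold = 1e-8) {
  d <- dim(Fe)
  AFm <- A %*% fe_as_matrix(Fe)
  AF <- array(AFm, dim = d)
  AFn <- if (length(Fn)) as.vector(A %*% Fn) else numeric(0)
  sv <- svd(S)
  pseudo <- min(sv$d) < threshold * max(sv$d)
  if (pseudo) {
    keep <- sv$d >= threshold * max(sv$d)
    S_inv <- sv$u[, keep, drop = FALSE] %*%
      (t(sv$v[, keep, drop = FALSE]) / sv$d[keep])
  } else {
    S_inv <- chol2inv(chol(S))
  }
  list(AF = AF, AFn = AFn, S_inv = S_inv, pseudoinverse = pseudo)
}

#' One-electron direct reaction field correction to the core Hamiltonian
#'
#' Assembles the nuclear-electron cross term and the electron
#' self-interaction. The self-interaction couples two field operators of the
#' same electron through `A`; the product is split by a resolution of the
#' identity over the primary basis. In the default `"exact-same-site"` mode
#' the same-site (`i = j`) RI contributions are removed and replaced by exact
#' core-polarization-potential integrals weighted by the diagonal 3x3 blocks
#' of `A`; `"pure-ri"` keeps the RI approximation throughout.
#'
#' @param Fe,Fn,A As in [build_intermediates()].
#' @param AF,AFn,S_inv Intermediates from [build_intermediates()].
#' @param cpp CPP integral array from [cpp_integrals()] (required in
#'   exact-same-site mode).
#' @param ri_mode `"exact-same-site"` or `"pure-ri"`.
#' @return Symmetric `n_ao x n_ao` matrix `H_pol`.
#' @export
one_electron_correction <- function(Fe, Fn, AF, AFn, S_inv, cpp = NULL, A,
                                    ri_mode = c("exact-same-site", "pure-ri")) {
  ri_mode <- match.arg(ri_mode)
  n <- dim(Fe)[2]
  np3 <- dim(Fe)[1]
  H <- matrix(0, n, n)
  if (np3 == 0) return(H)
  # cross term: -sum_{i a} AFn_{ia} F_{ia}
  Fm <- fe_as_matrix(Fe)
  H <- H - matrix(as.vector(t(Fm) %*% AFn), n, n)
  # RI self-interaction: -1/2 sum_{ia} F_ia S^-1 AF_ia
  for (k in seq_len(np3)) {
    Fk <- matrix(Fe[k, , ], n, n)
    Gk <- matrix(AF[k, , ], n, n)
    H <- H - 0.5 * (Fk %*% S_inv %*% Gk)
  }
  if (ri_mode == "exact-same-site") {
    if (is.null(cpp)) stop("exact-same-site mode requires CPP integrals")
    ns <- np3 / 3
    for (i in seq_len(ns)) {
      Aii <- A[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)]
      for (alpha in 1:3) for (beta in 1:3) {
        if (Aii[alpha, beta] == 0) next
        Fa <- matrix(Fe[3 * (i - 1) + alpha, , ], n, n)
        Fb <- matrix(Fe[3 * (i - 1) + beta, , ], n, n)
        H <- H - 0.5 * Aii[alpha, beta] *
          (matrix(cpp[alpha, beta, i, , ], n, n) - Fa %*% S_inv %*% Fb)
      }
    }
  }
  (H + t(H)) / 2
}

#' Factorized Coulomb correction
#'
#' Contraction of the two-electron polarization tensor with a density matrix
#' in the Coulomb pattern, computed through the factorized route (never
#' materializing the four-index tensor):
#' \deqn{\Delta J_{\mu\nu} = \sum_{\lambda\sigma}
#'   (\mu\nu|\lambda\sigma)_{pol} D_{\lambda\sigma}
#'   = -\sum_{i\alpha} (AF)_{i\alpha,\mu\nu} \sum_{\lambda\sigma}
#'     F_{i\alpha,\lambda\sigma} D_{\lambda\sigma}.}
#' `D` may be any real matrix (generalized builds).
#'
#' @param D Density-like matrix (`n_ao x n_ao`).
#' @param Fe Field-integral array.
#' @param AF Intermediate from [build_intermediates()].
#' @return `n_ao x n_ao` matrix.
#' @export
delta_J <- function(D, Fe, AF) {
  n <- dim(Fe)[2]
  stopifnot(nrow(D) == n, ncol(D) == n)
  if (dim(Fe)[1] == 0) return(matrix(0, n, n))
  FD <- as.vector(fe_as_matrix(Fe) %*% as.vector(D))
  -matrix(as.vector(t(fe_as_matrix(AF)) %*% FD), n, n)
}

#' Factorized exchange correction
#'
#' Exchange-pattern contraction
#' \deqn{\Delta K_{\mu\nu} = \sum_{\lambda\sigma}
#'   (\mu\lambda|\nu\sigma)_{pol} D_{\lambda\sigma}
#'   = -\sum_{i\alpha} [F_{i\alpha} D (AF)_{i\alpha}^T]_{\mu\nu}.}
#' The inner contraction scales as `N_pol x N_ao^3`.
#'
#' @inheritParams delta_J
#' @return `n_ao x n_ao` matrix.
#' @export
delta_K <- function(D, Fe, AF) {
  n <- dim(Fe)[2]
  stopifnot(nrow(D) == n, ncol(D) == n)
  K <- matrix(0, n, n)
  for (k in seq_len(dim(Fe)[1])) {
    Fk <- matrix(Fe[k, , ], n, n)
    Gk <- matrix(AF[k, , ], n, n)
    K <- K - Fk %*% D %*% t(Gk)
  }
  K
}

#' Explicit two-electron polarization tensor (oracle)
#'
#' Dense four-index tensor
#' \deqn{(\mu\nu|\lambda\sigma)_{pol} =
#'   -F^{(e)T}_{\mu\nu} A F^{(e)}_{\lambda\sigma},}
#' carrying the full 8-fold permutational symmetry of electron-repulsion
#' integrals. Only intended as the brute-force check of the factorized
#' [delta_J()] / [delta_K()] builds on tiny bases.
#'
#' @param Fe Field-integral array.
#' @param A Effective polarizability supermatrix.
#' @param max_nao Resource guard.
#' @return Array of dimension `n_ao^4`.
#' @export
explicit_two_electron_tensor <- function(Fe, A, max_nao = 8) {
  n <- dim(Fe)[2]
  if (n > max_nao)
    stop("explicit tensor refused for ", n, " AOs (guard: ", max_nao, ")")
  Fm <- fe_as_matrix(Fe)
  G <- -t(Fm) %*% A %*% Fm
  G <- (G + t(G)) / 2   # bra-ket exchange symmetry exact (A is symmetric)
  array(G, dim = rep(n, 4))
}
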