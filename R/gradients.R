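# Analytical gradients of the embedded RHF energy with respect to QM nuclei,
# MM point charges and polarizable sites.
#
# Strategy: every integral derivative with respect to a Gaussian center is
# obtained from the angular-momentum raising/lowering identity
#   d/dA_x <(i) ...> = 2a <(i+1_x) ...> - i <(i-1_x) ...>
# and derivatives with respect to operator centers (nuclei in V, sites in the
# polarization integrals) follow from translational invariance,
#   d/dR = -(d/dA + d/dB).
# The polarization pieces are organised exactly as contraction functions: an
# E supertensor (3 N_pol x N_ao x N_ao) multiplies field-integral
# derivatives, a U supermatrix (3 N_pol x 3 N_pol) multiplies the gradient of
# the effective polarizability through dA/dx = A (dT/dx) A, and the overlap
# dependence of the RI term enters through dS^-1 = -S^-1 dS S^-1. Derivative
# arrays are contracted on the fly and never stored.

# ---- energy-weighted density ----------------------------------------------

#' Energy-weighted density matrix
#'
#' \deqn{W_{\mu\nu} = 2 \sum_{k\in occ} \epsilon_k C_{\mu k} C_{\nu k}}
#' (closed-shell occupation 2), the matrix that contracts with the overlap
#' derivative in the Pulay term of the SCF gradient.
#'
#' @param state Converged [run_rhf()] state.
#' @return Symmetric matrix of class `energy_weighted_density`.
#' @export
energy_weighted_density <- function(state) {
  if (!state$converged) stop("state is not converged; refusing")
  Co <- state$C[, seq_len(state$nocc), drop = FALSE]
  eo <- state$eps[seq_len(state$nocc)]
  W <- 2 * Co %*% (t(Co) * eo)
  structure((W + t(W)) / 2, class = "energy_weighted_density")
}

# ---- particle bookkeeping --------------------------------------------------

# rows of the gradient arrays: nuclei, then charges, then sites
particle_table <- function(system) {
  na <- nrow(system$molecule)
  nc <- nrow(system$env$charges)
  ns <- nrow(system$env$sites)
  tibble::tibble(
    kind = c(rep("nucleus", na), rep("charge", nc), rep("site", ns)),
    index = c(seq_len(na), seq_len(nc), seq_len(ns)))
}

particle_row <- function(system, kind, index) {
  na <- nrow(system$molecule)
  nc <- nrow(system$env$charges)
  switch(kind,
         nucleus = index,
         charge = na + index,
         site = na + nc + index,
         stop("unknown particle kind: ", kind))
}

zero_grad <- function(system) {
  matrix(0, nrow(particle_table(system)), 3)
}

# ---- primitive-pair center derivatives -------------------------------------

# derivative of a contracted pair integral w.r.t. component d of the center
# of slot 1 or 2; fn(a, A, la, b, B, lb) returns a numeric vector
pair_slot_deriv <- function(ao1, ao2, slot, d, fn) {
  acc <- NULL
  for (ip in seq_along(ao1$exps)) for (jp in seq_along(ao2$exps)) {
    cc <- ao1$coefs[ip] * ao2$coefs[jp]
    a <- ao1$exps[ip]; b <- ao2$exps[jp]
    la <- ao1$pows; lb <- ao2$pows
    if (slot == 1) {
      lp <- la; lp[d] <- lp[d] + 1
      v <- 2 * a * fn(a, ao1$center, lp, b, ao2$center, lb)
      if (la[d] > 0) {
        lm <- la; lm[d] <- lm[d] - 1
        v <- v - la[d] * fn(a, ao1$center, lm, b, ao2$center, lb)
      }
    } else {
      lp <- lb; lp[d] <- lp[d] + 1
      v <- 2 * b * fn(a, ao1$center, la, b, ao2$center, lp)
      if (lb[d] > 0) {
        lm <- lb; lm[d] <- lm[d] - 1
        v <- v - lb[d] * fn(a, ao1$center, la, b, ao2$center, lm)
      }
    }
    acc <- if (is.null(acc)) cc * v else acc + cc * v
  }
  acc
}

# all six center derivatives (2 slots x 3 components) of a scalar kernel
pair_center_derivs <- function(ao1, ao2, fn) {
  out <- array(0, dim = c(2, 3))
  for (slot in 1:2) for (d in 1:3) {
    out[slot, d] <- pair_slot_deriv(ao1, ao2, slot, d, fn)
  }
  out
}

# ---- standard one-electron and ERI gradient accumulators -------------------

# sum_{mu nu} M_{mu nu} d(T + V_ne + V_mm)_{mu nu}/dx for every particle
grad_core_hamiltonian <- function(system, M) {
  g <- zero_grad(system)
  basis <- system$basis
  n <- length(basis)
  nuc <- as.matrix(system$molecule[, c("x", "y", "z")])
  Z <- system$molecule$Z
  qpos <- charge_positions(system$env)
  qq <- system$env$charges$q
  sources <- rbind(nuc, qpos)
  scharge <- c(Z, qq)
  skind <- c(rep("nucleus", nrow(nuc)), rep("charge", length(qq)))
  sidx <- c(seq_len(nrow(nuc)), seq_len(length(qq)))

  for (mu in seq_len(n)) for (nu in mu:n) {
    w <- M[mu, nu] * (if (mu == nu) 1 else 2)
    if (abs(w) < 1e-16) next
    ao1 <- basis[[mu]]; ao2 <- basis[[nu]]
    # kinetic: centers only
    dk <- pair_center_derivs(ao1, ao2, prim_kinetic)
    g[particle_row(system, "nucleus", ao1$atom), ] <-
      g[particle_row(system, "nucleus", ao1$atom), ] + w * dk[1, ]
    g[particle_row(system, "nucleus", ao2$atom), ] <-
      g[particle_row(system, "nucleus", ao2$atom), ] + w * dk[2, ]
    # attraction to every source: center parts + source part by translation
    for (s in seq_len(nrow(sources))) {
      if (scharge[s] == 0) next
      C <- sources[s, ]
      dv <- pair_center_derivs(ao1, ao2, function(a, A, la, b, B, lb)
        prim_nuc(a, A, la, b, B, lb, C))
      dv <- -scharge[s] * dv          # V = -q <1/|r-C|>
      g[particle_row(system, "nucleus", ao1$atom), ] <-
        g[particle_row(system, "nucleus", ao1$atom), ] + w * dv[1, ]
      g[particle_row(system, "nucleus", ao2$atom), ] <-
        g[particle_row(system, "nucleus", ao2$atom), ] + w * dv[2, ]
      g[particle_row(system, skind[s], sidx[s]), ] <-
        g[particle_row(system, skind[s], sidx[s]), ] - w * (dv[1, ] + dv[2, ])
    }
  }
  g
}

# sum_{mu nu} M_{mu nu} dS_{mu nu}/dx
grad_overlap <- function(system, M) {
  g <- zero_grad(system)
  basis <- system$basis
  n <- length(basis)
  for (mu in seq_len(n)) for (nu in mu:n) {
    w <- M[mu, nu] * (if (mu == nu) 1 else 2)
    if (abs(w) < 1e-16) next
    ds <- pair_center_derivs(basis[[mu]], basis[[nu]], prim_overlap)
    g[particle_row(system, "nucleus", basis[[mu]]$atom), ] <-
      g[particle_row(system, "nucleus", basis[[mu]]$atom), ] + w * ds[1, ]
    g[particle_row(system, "nucleus", basis[[nu]]$atom), ] <-
      g[particle_row(system, "nucleus", basis[[nu]]$atom), ] + w * ds[2, ]
  }
  g
}

# sum_{pqrs} Gamma_{pqrs} d(pq|rs)/dx via unique quartets; Gamma is the
# full two-particle density-like weight (no symmetry assumed; the orbit sum
# handles it). One shared Hermite table per primitive quartet serves all
# twelve center-derivative components (eri_quartet_engine).
grad_eri <- function(system, Gamma) {
  g <- zero_grad(system)
  basis <- system$basis
  n <- length(basis)
  atoms <- vapply(basis, function(a) a$atom, 1L)
  nat <- length(unique(atoms))
  if (nat == 1) return(g)   # all centers coincide: translational invariance
  pd <- vector("list", n * n)
  pget <- function(i, j) {
    key <- (i - 1) * n + j
    if (is.null(pd[[key]])) pd[[key]] <<- eri_pair_data(basis[[i]], basis[[j]],
                                                        deriv = TRUE)
    pd[[key]]
  }
  for (p in seq_len(n)) for (q in 1:p) for (r in 1:p) {
    smax <- if (r == p) q else r
    for (s in 1:smax) {
      # sum Gamma over the distinct permutations of this quartet
      perms <- unique(list(c(p, q, r, s), c(q, p, r, s), c(p, q, s, r),
                           c(q, p, s, r), c(r, s, p, q), c(s, r, p, q),
                           c(r, s, q, p), c(s, r, q, p)))
      wt <- sum(vapply(perms, function(ix) Gamma[ix[1], ix[2], ix[3], ix[4]],
                       1.0))
      if (abs(wt) < 1e-14) next
      qat <- c(atoms[p], atoms[q], atoms[r], atoms[s])
      if (length(unique(qat)) == 1) next
      dv <- eri_quartet_engine(pget(p, q), pget(r, s), deriv = TRUE)$deriv
      for (slot in 1:4) {
        row <- particle_row(system, "nucleus", qat[slot])
        g[row, ] <- g[row, ] + wt * dv[slot, ]
      }
    }
  }
  g
}

# ---- polarization integral derivative contractions -------------------------

#' Field-integral derivative contraction
#'
#' Contracts the derivatives of the damped electric-field integrals with a
#' supertensor `E` of shape `(3 N_pol, N_ao, N_ao)` in a single integral-
#' direct pass, returning the per-particle gradient array
#' \eqn{\sum_{i\alpha\mu\nu} E_{i\alpha,\mu\nu}\,
#'   \partial F^{(e)}_{i\alpha,\mu\nu}/\partial x}.
#' Site derivatives follow from translational invariance of the integral.
#'
#' @param system System list from a [run_rhf()] state (`state$system`).
#' @param E Weight supertensor (A-weighted density products).
#' @return Matrix (n_particles x 3), rows ordered nuclei, charges, sites.
#' @export
field_integral_derivative_contraction <- function(system, E) {
  g <- zero_grad(system)
  ns <- nrow(system$env$sites)
  if (ns == 0) return(g)
  basis <- system$basis
  n <- length(basis)
  Rs <- site_positions(system$env)
  r0 <- system$env$sites$r0
  for (i in seq_len(ns)) {
    Ei <- E[(3 * i - 2):(3 * i), , , drop = FALSE]
    if (max(abs(Ei)) < 1e-16) next
    for (mu in seq_len(n)) for (nu in mu:n) {
      sym <- if (mu == nu) 1 else 2
      w <- 0.5 * (Ei[, mu, nu] + Ei[, nu, mu]) * sym   # 3-vector over alpha
      if (max(abs(w)) < 1e-16) next
      ao1 <- basis[[mu]]; ao2 <- basis[[nu]]
      fn <- function(a, A, la, b, B, lb)
        prim_field(a, A, la, b, B, lb, Rs[i, ], r0[i])
      dsum <- numeric(3)
      for (slot in 1:2) {
        ao <- if (slot == 1) ao1 else ao2
        row <- particle_row(system, "nucleus", ao$atom)
        for (d in 1:3) {
          dv <- sum(w * pair_slot_deriv(ao1, ao2, slot, d, fn))
          g[row, d] <- g[row, d] + dv
          dsum[d] <- dsum[d] + dv
        }
      }
      row <- particle_row(system, "site", i)
      g[row, ] <- g[row, ] - dsum
    }
  }
  g
}

# CPP derivative contraction: weights Wc[alpha, beta, i, mu, nu]
grad_cpp_contraction <- function(system, Wc) {
  g <- zero_grad(system)
  ns <- nrow(system$env$sites)
  if (ns == 0 || is.null(system$cpp)) return(g)
  basis <- system$basis
  n <- length(basis)
  Rs <- site_positions(system$env)
  r0 <- system$env$sites$r0
  for (i in seq_len(ns)) {
    for (mu in seq_len(n)) for (nu in mu:n) {
      sym <- if (mu == nu) 1 else 2
      w <- 0.5 * (Wc[, , i, mu, nu] + t(Wc[, , i, nu, mu])) * sym  # 3x3
      if (max(abs(w)) < 1e-16) next
      ao1 <- basis[[mu]]; ao2 <- basis[[nu]]
      fn <- function(a, A, la, b, B, lb)
        as.vector(prim_cpp(a, A, la, b, B, lb, Rs[i, ], r0[i]))
      dsum <- numeric(3)
      for (slot in 1:2) {
        ao <- if (slot == 1) ao1 else ao2
        row <- particle_row(system, "nucleus", ao$atom)
        for (d in 1:3) {
          dv <- sum(as.vector(w) * pair_slot_deriv(ao1, ao2, slot, d, fn))
          g[row, d] <- g[row, d] + dv
          dsum[d] <- dsum[d] + dv
        }
      }
      row <- particle_row(system, "site", i)
      g[row, ] <- g[row, ] - dsum
    }
  }
  g
}

# ---- effective polarizability derivative contraction -----------------------

# derivative of the Thole-damped dipole tensor block T^(ij) w.r.t. r = Ri - Rj
thole_block_deriv <- function(rvec, alpha_i, alpha_j, a, damping) {
  r <- sqrt(sum(rvec * rvec))
  out <- array(0, dim = c(3, 3, 3))   # [gamma, delta, d]
  if (damping == "thole") {
    s <- (alpha_i * alpha_j)^(1 / 6)
    x <- a * r / s
    ex <- exp(-x)
    l3 <- 1 - ex * (1 + x + x^2 / 2)
    l5 <- 1 - ex * (1 + x + x^2 / 2 + x^3 / 6)
    dl3 <- ex * x^2 / 2 * (a / s)
    dl5 <- ex * x^3 / 6 * (a / s)
  } else {
    l3 <- l5 <- 1; dl3 <- dl5 <- 0
  }
  for (d in 1:3) {
    rd <- rvec[d] / r
    for (g1 in 1:3) for (g2 in 1:3) {
      v <- 3 * dl5 * rd * rvec[g1] * rvec[g2] / r^5 +
        3 * l5 * ((g1 == d) * rvec[g2] + (g2 == d) * rvec[g1]) / r^5 -
        15 * l5 * rvec[g1] * rvec[g2] * rvec[d] / r^7 -
        dl3 * rd * (g1 == g2) / r^3 +
        3 * l3 * (g1 == g2) * rvec[d] / r^5
      out[g1, g2, d] <- v
    }
  }
  out
}

#' Effective-polarizability derivative contraction
#'
#' Uses the matrix identity `dA/dx = A (dT/dx) A` (atomic polarizabilities
#' are geometry-independent) to contract a supermatrix `U` with the gradient
#' of the effective polarizability:
#' \eqn{\sum_{i\alpha j\beta} U_{i\alpha,j\beta}\,
#'   \partial A_{i\alpha,j\beta}/\partial x
#'   = \sum (A U A) \circ \partial T/\partial x}.
#' Only polarizable-site displacements contribute; the Thole damping factors
#' are differentiated along with the bare tensor.
#'
#' @param system System list.
#' @param U Weight supermatrix (`3 N_pol x 3 N_pol`).
#' @return Per-particle gradient array (nonzero only in site rows).
#' @export
polarizability_derivative_contraction <- function(system, U) {
  g <- zero_grad(system)
  ns <- nrow(system$env$sites)
  if (ns < 2) return(g)
  A <- system$A
  AUA <- A %*% ((U + t(U)) / 2) %*% A
  sites <- system$env$sites
  Rs <- site_positions(system$env)
  damping <- attr(system$Tarr, "damping")
  a <- attr(system$Tarr, "thole_a")
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    rvec <- Rs[i, ] - Rs[j, ]
    dT <- thole_block_deriv(rvec, sites$alpha[i], sites$alpha[j], a, damping)
    blk <- AUA[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] +
      t(AUA[(3 * j - 2):(3 * j), (3 * i - 2):(3 * i)])
    for (d in 1:3) {
      v <- sum(blk * dT[, , d])
      g[particle_row(system, "site", i), d] <-
        g[particle_row(system, "site", i), d] + v
      g[particle_row(system, "site", j), d] <-
        g[particle_row(system, "site", j), d] - v
    }
  }
  g
}

# ---- classical field (F^n) chain -------------------------------------------

# sum_{i alpha} v_{i alpha} dFn_{i alpha}/dx for all particles; Fn is the
# damped field of nuclei and MM charges at the sites
grad_fn_chain <- function(system, v) {
  g <- zero_grad(system)
  ns <- nrow(system$env$sites)
  if (ns == 0 || max(abs(v)) == 0) return(g)
  Rs <- site_positions(system$env)
  r0 <- system$env$sites$r0
  nuc <- as.matrix(system$molecule[, c("x", "y", "z")])
  Z <- system$molecule$Z
  qpos <- charge_positions(system$env)
  qq <- system$env$charges$q
  sources <- rbind(nuc, qpos)
  scharge <- c(Z, qq)
  skind <- c(rep("nucleus", nrow(nuc)), rep("charge", length(qq)))
  sidx <- c(seq_len(nrow(nuc)), seq_len(length(qq)))
  nq <- nrow(nuc)
  for (i in seq_len(ns)) {
    vi <- v[(3 * i - 2):(3 * i)]
    for (s in seq_len(nrow(sources))) {
      if (scharge[s] == 0) next
      if (s > nq && ncol(system$env$excl) >= i && system$env$excl[s - nq, i]) next
      rvec <- Rs[i, ] - sources[s, ]
      r <- sqrt(sum(rvec * rvec))
      if (r < 1e-12) next
      C <- field_damping(r, r0[i])
      dC <- field_damping_deriv(r, r0[i])
      # d f_gamma / d r_d with f = Q C(r) r_gamma / r^3
      df <- matrix(0, 3, 3)
      for (gm in 1:3) for (d in 1:3) {
        df[gm, d] <- scharge[s] *
          (dC * (rvec[d] / r) * rvec[gm] / r^3 +
             C * ((gm == d) / r^3 - 3 * rvec[gm] * rvec[d] / r^5))
      }
      contrib <- as.vector(t(df) %*% vi)   # contribution per displacement d
      g[particle_row(system, "site", i), ] <-
        g[particle_row(system, "site", i), ] + contrib
      g[particle_row(system, skind[s], sidx[s]), ] <-
        g[particle_row(system, skind[s], sidx[s]), ] - contrib
    }
  }
  g
}

# classical Coulomb forces: nuclear-nuclear, nuclear-charge, (charge-charge)
grad_classical <- function(system) {
  g <- zero_grad(system)
  nuc <- as.matrix(system$molecule[, c("x", "y", "z")])
  Z <- system$molecule$Z
  qpos <- charge_positions(system$env)
  qq <- system$env$charges$q
  pos <- rbind(nuc, qpos)
  q <- c(Z, qq)
  kind <- c(rep("nucleus", nrow(nuc)), rep("charge", length(qq)))
  idx <- c(seq_len(nrow(nuc)), seq_len(length(qq)))
  np <- nrow(pos)
  inc_qq <- isTRUE(system$options$include_mm_coulomb)
  if (np < 2) return(g)
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    if (kind[i] == "charge" && kind[j] == "charge" && !inc_qq) next
    rvec <- pos[i, ] - pos[j, ]
    r <- sqrt(sum(rvec * rvec))
    f <- -q[i] * q[j] * rvec / r^3       # dE/dR_i of q_i q_j / r
    g[particle_row(system, kind[i], idx[i]), ] <-
      g[particle_row(system, kind[i], idx[i]), ] + f
    g[particle_row(system, kind[j], idx[j]), ] <-
      g[particle_row(system, kind[j], idx[j]), ] - f
  }
  g
}

# ---- J/K polarization gradient corrections ---------------------------------

#' Gradient corrections of the polarization Coulomb/exchange builds
#'
#' Assembles \eqn{d\,\mathrm{Tr}(D_1^T \Delta J(D_2))/dx} and
#' \eqn{d\,\mathrm{Tr}(D_1^T \Delta K(D_2))/dx} for two (possibly different,
#' possibly non-symmetric) density-like matrices, from the field-integral
#' and polarizability contraction primitives, including the transpose terms
#' of the exchange pattern. Keeping two labels is the seam for response-type
#' gradients; RHF uses `D1 = D2 = D`.
#'
#' @param system System list.
#' @param D1,D2 Density-like matrices.
#' @return List of per-particle gradient arrays `dJ` and `dK`.
#' @export
jk_gradient_corrections <- function(system, D1, D2) {
  n <- length(system$basis)
  np3 <- dim(system$Fe)[1]
  if (np3 == 0) {
    return(list(dJ = zero_grad(system), dK = zero_grad(system)))
  }
  Fm <- fe_as_matrix(system$Fe)
  A <- system$A
  Fd1 <- as.vector(Fm %*% as.vector(D1))
  Fd2 <- as.vector(Fm %*% as.vector(D2))
  AFd1 <- as.vector(A %*% Fd1)
  AFd2 <- as.vector(A %*% Fd2)

  # Coulomb: Tr(D1' dJ(D2)) = -(F d1)' A (F d2)
  EJ <- array(0, dim = dim(system$Fe))
  for (k in seq_len(np3)) {
    EJ[k, , ] <- -(AFd2[k] * D1 + AFd1[k] * D2)
  }
  UJ <- -tcrossprod(Fd1, Fd2)
  gJ <- field_integral_derivative_contraction(system, EJ) +
    polarizability_derivative_contraction(system, UJ)

  # Exchange: Tr(D1' dK(D2)) = -sum_{ia jb} A Tr(D1' F_ia D2 F_jb)
  AF <- system$inter$AF
  EK <- array(0, dim = dim(system$Fe))
  UK <- matrix(0, np3, np3)
  Fmats <- lapply(seq_len(np3), function(k) matrix(system$Fe[k, , ], n, n))
  AFmats <- lapply(seq_len(np3), function(k) matrix(AF[k, , ], n, n))
  for (k in seq_len(np3)) {
    EK[k, , ] <- -(D2 %*% AFmats[[k]] %*% t(D1) + t(D1) %*% AFmats[[k]] %*% D2)
  }
  for (k in seq_len(np3)) {
    M1 <- t(D1) %*% Fmats[[k]] %*% D2
    for (l in seq_len(np3)) {
      UK[k, l] <- -sum(M1 * Fmats[[l]])
    }
  }
  gK <- field_integral_derivative_contraction(system, EK) +
    polarizability_derivative_contraction(system, UK)
  list(dJ = gJ, dK = gK)
}

# ---- total gradient --------------------------------------------------------

#' Total analytical gradient of the embedded RHF energy
#'
#' Full gradient with respect to every QM nucleus, MM point charge and
#' polarizable site: the standard RHF terms (core Hamiltonian, two-electron,
#' Pulay overlap), the polarization corrections (field-integral, CPP,
#' effective-polarizability and RI-overlap chains), the classical damped
#' field chain of the zero-electron term, and the classical Coulomb forces.
#' For an isolated system the components sum to zero (translational
#' invariance).
#'
#' @param state Converged [run_rhf()] state.
#' @return Object of class `gradient_report`: tibble `particles` with
#'   `kind`, `index`, `gx`, `gy`, `gz` (hartree/bohr) and a `breakdown`
#'   list of per-term arrays.
#' @export
total_gradient <- function(state) {
  if (!state$converged) stop("state is not converged; refusing")
  system <- state$system
  n <- length(system$basis)
  D <- state$D
  W <- unclass(energy_weighted_density(state))

  # standard terms
  g_core <- grad_core_hamiltonian(system, D)
  g_ov <- grad_overlap(system, -W)
  Gamma <- 0.5 * outer_dens(D, D) - 0.25 * outer_exch(D, D)
  g_eri <- grad_eri(system, Gamma)
  g_cl <- grad_classical(system)

  np3 <- dim(system$Fe)[1]
  g_hpol <- zero_grad(system)
  g_jkpol <- zero_grad(system)
  g_e0 <- zero_grad(system)
  if (np3 > 0) {
    A <- system$A
    ns <- np3 / 3
    Fm <- fe_as_matrix(system$Fe)
    Fn <- system$Fn
    AFn <- system$inter$AFn
    S_inv <- system$inter$S_inv
    d <- as.vector(D)
    Fd <- as.vector(Fm %*% d)
    AFd <- as.vector(A %*% Fd)
    exact_ss <- system$options$ri_mode == "exact-same-site"
    At <- A
    if (exact_ss) {
      for (i in seq_len(ns)) {
        At[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)] <- 0
      }
    }
    Fmats <- lapply(seq_len(np3), function(k) matrix(system$Fe[k, , ], n, n))
    AtF <- array(At %*% Fm, dim = dim(system$Fe))
    AtFmats <- lapply(seq_len(np3), function(k) matrix(AtF[k, , ], n, n))

    # --- one-electron polarization (cross + RI + exact same-site CPP) ---
    E1 <- array(0, dim = dim(system$Fe))
    for (k in seq_len(np3)) {
      E1[k, , ] <- -AFn[k] * D -
        0.5 * (S_inv %*% AtFmats[[k]] %*% D + D %*% AtFmats[[k]] %*% S_inv)
    }
    g_hpol <- g_hpol + field_integral_derivative_contraction(system, E1)

    # U from cross, RI and exact same-site terms
    U1 <- -0.5 * (tcrossprod(Fn, Fd) + tcrossprod(Fd, Fn))
    Rri <- matrix(0, np3, np3)
    for (k in seq_len(np3)) {
      DFSk <- D %*% Fmats[[k]] %*% S_inv
      for (l in seq_len(np3)) {
        Rri[k, l] <- sum(DFSk * t(Fmats[[l]]))  # Tr(D F_k S^-1 F_l)
      }
    }
    if (exact_ss) {
      Uri <- -0.5 * Rri
      for (i in seq_len(ns)) {
        ii <- (3 * i - 2):(3 * i)
        Uri[ii, ii] <- 0
        for (al in 1:3) for (be in 1:3) {
          Uri[ii[al], ii[be]] <- -0.5 *
            sum(D * matrix(system$cpp[al, be, i, , ], n, n))
        }
      }
    } else {
      Uri <- -0.5 * Rri
    }
    g_hpol <- g_hpol + polarizability_derivative_contraction(system, U1 + Uri)

    # CPP integral derivatives (exact same-site mode only)
    if (exact_ss) {
      Wc <- array(0, dim = c(3, 3, ns, n, n))
      for (i in seq_len(ns)) {
        Aii <- A[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)]
        for (al in 1:3) for (be in 1:3) {
          Wc[al, be, i, , ] <- -0.5 * Aii[al, be] * D
        }
      }
      g_hpol <- g_hpol + grad_cpp_contraction(system, Wc)
    }

    # RI overlap chain: dS^-1 = -S^-1 dS S^-1 inside the RI self-energy
    Ymat <- matrix(0, n, n)
    for (k in seq_len(np3)) {
      Ymat <- Ymat + 0.5 * (S_inv %*% AtFmats[[k]] %*% D %*% Fmats[[k]] %*% S_inv)
    }
    Ymat <- (Ymat + t(Ymat)) / 2
    g_hpol <- g_hpol + grad_overlap(system, Ymat)

    # F^n chain from the cross term (hpol) and the zero-electron term (e0)
    g_hpol <- g_hpol + grad_fn_chain(system, -AFd)
    g_e0 <- g_e0 + grad_fn_chain(system, -AFn) +
      polarizability_derivative_contraction(system, -0.5 * tcrossprod(Fn, Fn))

    # --- two-electron polarization: 1/2 Tr(D dJ(D)) - 1/4 Tr(D dK(D)) ---
    jk <- jk_gradient_corrections(system, D, D)
    g_jkpol <- 0.5 * jk$dJ - 0.25 * jk$dK
  }

  gtot <- g_core + g_ov + g_eri + g_cl + g_hpol + g_jkpol + g_e0
  pt <- particle_table(system)
  pt$gx <- gtot[, 1]; pt$gy <- gtot[, 2]; pt$gz <- gtot[, 3]
  structure(list(
    particles = pt,
    gradient = gtot,
    breakdown = list(core = g_core, overlap = g_ov, eri = g_eri,
                     classical = g_cl, h_pol = g_hpol, jk_pol = g_jkpol,
                     e0_pol = g_e0)
  ), class = "gradient_report")
}

#' @export
print.gradient_report <- function(x, ...) {
  cat("<gradient_report> ", nrow(x$particles), " particles; max |g| = ",
      format(max(abs(x$gradient)), digits = 6), " hartree/bohr; net force = (",
      paste(format(colSums(x$gradient), digits = 3), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# two-particle density weights for the standard ERI gradient
outer_dens <- function(D1, D2) {
  n <- nrow(D1)
  array(outer(as.vector(D1), as.vector(D2)), dim = rep(n, 4))
}

outer_exch <- function(D1, D2) {
  n <- nrow(D1)
  G <- array(0, dim = rep(n, 4))
  for (p in seq_len(n)) for (q in seq_len(n)) {
    G[p, q, , ] <- tcrossprod(D1[p, ], D2[q, ])
  }
  G
}
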