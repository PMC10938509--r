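# Minimal restricted Hartree-Fock engine with direct reaction field
# corrections folded into the core Hamiltonian and the J/K builds. Dense,
# desk-scale: full diagonalization, DIIS with damping fallback, optional
# overlap pseudoinverse for near-linear-dependent bases.

#' Default SCF options
#'
#' @param max_iter Maximum SCF iterations.
#' @param conv_commutator Convergence threshold on `max |FDS - SDF|`.
#' @param conv_energy Convergence threshold on the energy change (hartree).
#' @param diis Use DIIS acceleration (plain damping fallback otherwise).
#' @param diis_size DIIS subspace size.
#' @param damping Mixing factor for the pre-DIIS damping steps.
#' @param charge Total molecular charge.
#' @param ri_mode Same-site treatment in the one-electron correction:
#'   `"exact-same-site"` (default) or `"pure-ri"`.
#' @param include_mm_coulomb Include the MM charge-charge Coulomb energy in
#'   the total (off by default: it is constant for fixed MM geometry).
#' @return Named list of options.
#' @export
scf_options <- function(max_iter = 200, conv_commutator = 1e-8,
                        conv_energy = 1e-10, diis = TRUE, diis_size = 8,
                        damping = 0.3, charge = 0,
                        ri_mode = c("exact-same-site", "pure-ri"),
                        include_mm_coulomb = FALSE) {
  list(max_iter = max_iter, conv_commutator = conv_commutator,
       conv_energy = conv_energy, diis = diis, diis_size = diis_size,
       damping = damping, charge = charge, ri_mode = match.arg(ri_mode),
       include_mm_coulomb = include_mm_coulomb)
}

# assemble every geometry/basis-dependent quantity needed by the SCF and the
# gradients; this is the single source of integrals for both
build_system <- function(molecule, basis = "sto-3g", environment = NULL,
                         options = scf_options()) {
  options <- modifyList(scf_options(), options)
  if (!("Z" %in% names(molecule))) {
    molecule$Z <- ELEMENT_Z[molecule$element]
    if (any(is.na(molecule$Z))) stop("unknown element in molecule")
  }
  if (is.character(basis) || !inherits(basis, "ao_basis")) {
    basis <- build_basis(molecule, basis)
  }
  lmax <- max(vapply(basis, function(a) sum(a$pows), 1L))
  if (lmax > 1) stop("only s and p shells are supported")
  if (is.null(environment)) environment <- pol_environment()

  nuc <- as.matrix(molecule[, c("x", "y", "z")])
  Z <- molecule$Z
  ints <- overlap_kinetic_nuclear(basis, nuc, Z)
  n <- length(basis)
  Vmm <- matrix(0, n, n)
  if (nrow(environment$charges) > 0) {
    Vmm <- overlap_kinetic_nuclear(basis, charge_positions(environment),
                                   environment$charges$q)$V
  }
  eri <- electron_repulsion(basis)
  Jmat <- matrix(eri, n * n, n * n)
  Kmat <- matrix(aperm(eri, c(1, 3, 2, 4)), n * n, n * n)

  ns <- nrow(environment$sites)
  if (ns > 0) {
    Tarr <- build_dipole_field_tensor(environment$sites, "thole",
                                      environment$thole_a)
    A <- build_effective_polarizability(environment$sites, Tarr,
                                        thole_a = environment$thole_a)
    Fe <- damped_field_integrals(basis, environment$sites)
    Fn <- nuclear_field_vectors(nuc, Z, environment)
    cpp <- if (options$ri_mode == "exact-same-site") {
      cpp_integrals(basis, environment$sites)
    } else NULL
    inter <- build_intermediates(Fe, Fn, A, ints$S)
    H_pol <- one_electron_correction(Fe, Fn, inter$AF, inter$AFn, inter$S_inv,
                                     cpp, A, options$ri_mode)
    E0_pol <- zero_electron_term(A, Fn)
  } else {
    Tarr <- NULL; A <- matrix(0, 0, 0)
    Fe <- array(0, dim = c(0, n, n)); Fn <- numeric(0)
    cpp <- NULL; inter <- list(AF = array(0, dim = c(0, n, n)),
                               AFn = numeric(0), S_inv = NULL)
    H_pol <- matrix(0, n, n)
    E0_pol <- 0
  }

  nelec <- sum(Z) - options$charge
  if (nelec %% 2 != 0) stop("odd electron count: restricted closed-shell only")

  # classical Coulomb terms (undamped monopole electrostatics)
  E_nn <- pair_coulomb(nuc, Z)
  E_nq <- cross_coulomb(nuc, Z, charge_positions(environment),
                        environment$charges$q)
  E_qq <- if (options$include_mm_coulomb) {
    pair_coulomb(charge_positions(environment), environment$charges$q)
  } else 0

  list(molecule = tibble::as_tibble(molecule), basis = basis,
       env = environment, options = options,
       S = ints$S, T = ints$T, Vnuc = ints$V, Vmm = Vmm,
       linear_dependence = ints$linear_dependence,
       eri = eri, Jmat = Jmat, Kmat = Kmat,
       Tarr = Tarr, A = A, Fe = Fe, Fn = Fn, cpp = cpp, inter = inter,
       H_pol = H_pol, E0_pol = E0_pol,
       nelec = nelec, E_nn = E_nn, E_nq = E_nq, E_qq = E_qq)
}

pair_coulomb <- function(pos, q) {
  if (is.null(pos) || nrow(pos) < 2) return(0)
  e <- 0
  for (i in seq_len(nrow(pos) - 1)) for (j in (i + 1):nrow(pos)) {
    if (q[i] * q[j] == 0) next
    e <- e + q[i] * q[j] / sqrt(sum((pos[i, ] - pos[j, ])^2))
  }
  e
}

cross_coulomb <- function(pos1, q1, pos2, q2) {
  if (is.null(pos1) || is.null(pos2) || nrow(pos1) == 0 || nrow(pos2) == 0)
    return(0)
  e <- 0
  for (i in seq_len(nrow(pos1))) for (j in seq_len(nrow(pos2))) {
    if (q1[i] * q2[j] == 0) next
    e <- e + q1[i] * q2[j] / sqrt(sum((pos1[i, ] - pos2[j, ])^2))
  }
  e
}

# J/K contraction against an arbitrary density-like matrix
contract_jk <- function(system, D) {
  n <- nrow(D)
  J <- matrix(system$Jmat %*% as.vector(D), n, n)
  K <- matrix(system$Kmat %*% as.vector(D), n, n)
  if (dim(system$Fe)[1] > 0) {
    J <- J + delta_J(D, system$Fe, system$inter$AF)
    K <- K + delta_K(D, system$Fe, system$inter$AF)
  }
  list(J = J, K = K)
}

#' Generalized Coulomb/exchange builds
#'
#' Coulomb- and exchange-like matrices, including the direct reaction field
#' corrections, contracted with an arbitrary real density-like matrix (not
#' necessarily symmetric or idempotent). For the converged RHF density these
#' are exactly the matrices entering the Fock operator; the generality is the
#' designed seam for response/CI layers.
#'
#' @param state A converged [run_rhf()] state (or a raw system list).
#' @param D Density-like matrix.
#' @return List with matrices `J` and `K` (corrections included).
#' @export
generalized_jk <- function(state, D) {
  system <- if (!is.null(state$system)) state$system else state
  contract_jk(system, D)
}

#' Restricted Hartree-Fock with direct reaction field embedding
#'
#' Solves the closed-shell SCF equations with the Fock operator
#' `F = H_core + H_pol + (J + dJ) - 1/2 (K + dK)`: point-charge electrostatic
#' embedding enters the core Hamiltonian, the polarizable environment enters
#' through the one- and two-electron reaction field corrections, and the
#' zero-electron constant (which contains the full MM polarization energy) is
#' added to the classical nuclear terms exactly once.
#'
#' @param molecule Data frame with `element`, `x`, `y`, `z` (bohr) — see
#'   [read_xyz()] for Angstrom input.
#' @param basis Basis name, file path, or [build_basis()] result.
#' @param environment Optional [pol_environment()].
#' @param options [scf_options()] overrides (plain list is fine).
#' @return Object of class `scf_state`: density `D`, MO coefficients `C`,
#'   orbital energies `eps`, total energy `E_total`, the component breakdown
#'   `E_components`, convergence flag/trace, and the underlying `system`.
#' @examples
#' h2 <- data.frame(element = c("H", "H"), x = 0, y = 0, z = c(0, 1.4))
#' st <- run_rhf(h2)
#' st$E_total   # about -1.1167 hartree
#' @export
run_rhf <- function(molecule, basis = "sto-3g", environment = NULL,
                    options = list()) {
  system <- build_system(molecule, basis, environment,
                         modifyList(scf_options(), options))
  scf_solve(system)
}

scf_solve <- function(system) {
  opt <- system$options
  n <- length(system$basis)
  H1 <- system$T + system$Vnuc + system$Vmm + system$H_pol
  S <- system$S

  es <- eigen(S, symmetric = TRUE)
  keep <- es$values > 1e-8 * max(es$values)
  X <- es$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(es$values[keep]),
                                                 sum(keep))
  nocc <- system$nelec / 2
  E_classical <- system$E_nn + system$E_nq + system$E_qq + system$E0_pol

  Fm <- H1
  E_old <- Inf
  D <- matrix(0, n, n)
  diis_F <- list(); diis_e <- list()
  trace <- list()
  converged <- FALSE
  n_iter <- 0
  E_elec <- 0

  for (it in seq_len(opt$max_iter)) {
    n_iter <- it
    Fo <- t(X) %*% Fm %*% X
    eo <- eigen((Fo + t(Fo)) / 2, symmetric = TRUE)
    ord <- order(eo$values)
    C <- X %*% eo$vectors[, ord, drop = FALSE]
    eps <- eo$values[ord]
    Co <- C[, seq_len(nocc), drop = FALSE]
    D_new <- 2 * tcrossprod(Co)
    D <- D_new
    jk <- contract_jk(system, D)
    F_new <- H1 + jk$J - 0.5 * jk$K
    E_elec <- 0.5 * sum(D * (H1 + F_new))
    err <- F_new %*% D %*% S - S %*% D %*% F_new
    err_max <- max(abs(err))
    dE <- abs(E_elec + E_classical - E_old)
    trace[[it]] <- c(iter = it, energy = E_elec + E_classical, error = err_max)
    if (err_max < opt$conv_commutator && dE < opt$conv_energy) {
      converged <- TRUE
      Fm <- F_new
      break
    }
    E_old <- E_elec + E_classical

    if (opt$diis) {
      diis_F[[length(diis_F) + 1]] <- F_new
      diis_e[[length(diis_e) + 1]] <- as.vector(err)
      if (length(diis_F) > opt$diis_size) {
        diis_F <- diis_F[-1]; diis_e <- diis_e[-1]
      }
      m <- length(diis_F)
      if (m >= 2) {
        B <- matrix(-1, m + 1, m + 1); B[m + 1, m + 1] <- 0
        for (i in seq_len(m)) for (j in seq_len(m)) {
          B[i, j] <- sum(diis_e[[i]] * diis_e[[j]])
        }
        rhs <- c(rep(0, m), -1)
        cf <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
        if (!is.null(cf) && all(is.finite(cf))) {
          Fm <- Reduce(`+`, Map(`*`, diis_F, cf))
        } else {
          Fm <- (1 - opt$damping) * F_new + opt$damping * Fm
        }
      } else {
        Fm <- F_new
      }
    } else {
      Fm <- (1 - opt$damping) * F_new + opt$damping * Fm
    }
  }
  if (!converged)
    warning("SCF did not converge in ", opt$max_iter, " iterations")

  Fo <- t(X) %*% Fm %*% X
  eo <- eigen((Fo + t(Fo)) / 2, symmetric = TRUE)
  ord <- order(eo$values)
  C <- X %*% eo$vectors[, ord, drop = FALSE]
  eps <- eo$values[ord]
  Co <- C[, seq_len(nocc), drop = FALSE]
  D <- 2 * tcrossprod(Co)
  jk <- contract_jk(system, D)
  Ffin <- H1 + jk$J - 0.5 * jk$K
  E_elec <- 0.5 * sum(D * (H1 + Ffin))
  E_total <- E_elec + E_classical

  state <- structure(list(
    D = D, C = C, eps = eps, nocc = nocc,
    F = Ffin, E_total = E_total,
    E_components = c(
      nuclear_repulsion = system$E_nn,
      nuclear_mm = system$E_nq,
      mm_mm = system$E_qq,
      E0_pol = system$E0_pol,
      one_electron = sum(D * (H1 - system$H_pol)),
      H_pol = sum(D * system$H_pol),
      two_electron = 0.5 * sum(D * (jk$J - 0.5 * jk$K))
    ),
    converged = converged, n_iter = n_iter,
    trace = tibble::as_tibble(do.call(rbind, trace)),
    system = system
  ), class = "scf_state")
  state
}

#' @export
print.scf_state <- function(x, ...) {
  cat("<scf_state> E_total = ", format(x$E_total, digits = 12), " hartree (",
      if (x$converged) "converged" else "NOT converged", " in ", x$n_iter,
      " iterations)\n", sep = "")
  ns <- nrow(x$system$env$sites)
  if (ns > 0) {
    mf <- state_polarization(x)
    cat("  ", ns, " polarizable sites; E0_pol = ",
        format(x$system$E0_pol, digits = 8), ", state E_pol = ",
        format(mf$E_pol_state, digits = 8), "\n", sep = "")
  }
  invisible(x)
}

#' State-dependent mean-field polarization
#'
#' For a converged state with density `D`, the expectation electric fields at
#' the polarizable sites are `f = F^(n) + sum_{mu nu} D_{mu nu}
#' F^(e)_{mu nu}` (the electron fields carry the electron charge sign), the
#' induced dipoles are `p = A f`, and the mean-field polarization energy is
#' `-1/2 f^T A f`. These are diagnostics: the energetics enter the SCF
#' through the Hamiltonian corrections, not through this mean field.
#'
#' @param state A [run_rhf()] result.
#' @return List of class `mean_field_response`: `fields`, `dipoles`
#'   (supervectors), `E_pol_state`, and a per-site tibble `sites`.
#' @export
state_polarization <- function(state) {
  system <- state$system
  ns <- nrow(system$env$sites)
  if (ns == 0) {
    return(structure(list(fields = numeric(0), dipoles = numeric(0),
                          E_pol_state = 0,
                          sites = tibble::tibble()),
                     class = "mean_field_response"))
  }
  f <- system$Fn + as.vector(fe_as_matrix(system$Fe) %*% as.vector(state$D))
  p <- induced_dipoles(system$A, f)
  E <- polarization_energy(system$A, f)
  sites <- system$env$sites
  pm <- matrix(p, ncol = 3, byrow = TRUE)
  tab <- tibble::tibble(id = sites$id, x = sites$x, y = sites$y, z = sites$z,
                        px = pm[, 1], py = pm[, 2], pz = pm[, 3],
                        p_norm = sqrt(rowSums(pm^2)))
  structure(list(fields = f, dipoles = p, E_pol_state = E, sites = tab),
            class = "mean_field_response")
}
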