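# Shared fixture builders and oracles for the test suite. Everything is
# generated in code; no binary data.

tight_opts <- list(conv_commutator = 1e-10, conv_energy = 1e-12)

mol_h2 <- function() {
  data.frame(element = c("H", "H"), x = c(0.1, -0.2), y = c(0, 0.3),
             z = c(0, 1.3))
}

mol_h2_sym <- function(r = 1.4) {
  data.frame(element = c("H", "H"), x = 0, y = 0, z = c(0, r))
}

mol_heh <- function() {
  data.frame(element = c("He", "H"), x = 0, y = 0, z = c(0, 1.46))
}

mol_h2o <- function() {
  ang <- 104.52 * pi / 180
  rOH <- 0.9572 * ANGSTROM_TO_BOHR
  data.frame(element = c("O", "H", "H"),
             x = c(0, rOH * sin(ang / 2), -rOH * sin(ang / 2)),
             y = 0, z = c(0, rOH * cos(ang / 2), rOH * cos(ang / 2)))
}

# environments of the fixture matrix: n_sites in {0, 1, 3}, n_charges {0, 2}
fixture_env <- function(n_sites, n_charges, alpha = c(1.1, 0.8, 1.4),
                        q = c(0.3, -0.3)) {
  charges <- if (n_charges > 0) {
    data.frame(id = 100 + seq_len(n_charges),
               x = c(2.0, -1.5)[seq_len(n_charges)],
               y = c(0.5, 1.0)[seq_len(n_charges)],
               z = c(2.5, -1.0)[seq_len(n_charges)],
               q = q[seq_len(n_charges)])
  } else NULL
  sites <- if (n_sites > 0) {
    data.frame(id = seq_len(n_sites),
               x = c(1.5, -1.0, 0.5)[seq_len(n_sites)],
               y = c(-0.5, 1.2, 2.0)[seq_len(n_sites)],
               z = c(2.5, -1.5, 3.0)[seq_len(n_sites)],
               alpha = alpha[seq_len(n_sites)])
  } else NULL
  pol_environment(charges = charges, sites = sites)
}

# a single normalized contracted Gaussian AO for integral tests
make_ao <- function(center, pows, exps, coefs = rep(1, length(exps))) {
  ao <- list(atom = 1L, center = center, pows = as.integer(pows), exps = exps,
             coefs = coefs * vapply(exps, polembed:::prim_norm, 1.0,
                                    pows = pows))
  s <- polembed:::ao_pair_overlap(ao, ao)
  ao$coefs <- ao$coefs / sqrt(s)
  ao
}

# displace one particle of a (molecule, environment) pair
displace <- function(mol, env, kind, index, dim, h) {
  col <- c("x", "y", "z")[dim]
  if (kind == "nucleus") mol[[col]][index] <- mol[[col]][index] + h
  if (kind == "charge") env$charges[[col]][index] <- env$charges[[col]][index] + h
  if (kind == "site") env$sites[[col]][index] <- env$sites[[col]][index] + h
  list(mol = mol, env = env)
}

# central finite difference of the total SCF energy
fd_energy_grad <- function(mol, env, kind, index, dim, h = 1e-4,
                           basis = "sto-3g", options = tight_opts) {
  p <- displace(mol, env, kind, index, dim, h)
  ep <- run_rhf(p$mol, basis, p$env, options)$E_total
  m <- displace(mol, env, kind, index, dim, -h)
  em <- run_rhf(m$mol, basis, m$env, options)$E_total
  (ep - em) / (2 * h)
}

# independent minimal RHF: fixed-point iteration assembled directly from the
# raw integral matrices, with symmetric orthogonalization and plain damping
# (no DIIS, no shared code with scf_solve beyond the integrals themselves)
reference_rhf <- function(S, Tm, V, eri, E_nn, nelec, n_iter = 300,
                          mix = 0.2) {
  n <- nrow(S)
  es <- eigen(S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values), n) %*% t(es$vectors)
  H1 <- Tm + V
  Fm <- H1
  D <- matrix(0, n, n)
  for (it in seq_len(n_iter)) {
    eo <- eigen(t(X) %*% Fm %*% X, symmetric = TRUE)
    ord <- order(eo$values)
    C <- X %*% eo$vectors[, ord, drop = FALSE]
    Co <- C[, seq_len(nelec / 2), drop = FALSE]
    D <- 2 * tcrossprod(Co)
    J <- K <- matrix(0, n, n)
    for (mu in 1:n) for (nu in 1:n) {
      J[mu, nu] <- sum(eri[mu, nu, , ] * D)
      K[mu, nu] <- sum(eri[mu, , nu, ] * D)
    }
    Fnew <- H1 + J - 0.5 * K
    Fm <- (1 - mix) * Fnew + mix * Fm
  }
  0.5 * sum(D * (H1 + Fm)) + E_nn
}

# brute-force solution of the coupled induced-dipole equations
# p_i = alpha_i (f_i + sum_{j != i} T^(ij) p_j), solved as a linear system
solve_dipoles_direct <- function(sites, f, damping = "thole",
                                 thole_a = 2.1304) {
  n <- nrow(sites)
  Tarr <- build_dipole_field_tensor(sites, damping, thole_a)
  M <- diag(3 * n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    M[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] <-
      -sites$alpha[i] * Tarr[, , i, j]
  }
  solve(M, rep(sites$alpha, each = 3) * f)
}

# Designed far-shell fixture for the coarse-graining checks: at each of K
# shell directions, three identical linear molecules oriented along mutually
# orthogonal axes at equal distance from the origin. The orthogonal triads
# cancel the leading (P2) orientation dependence of the molecular
# polarizability, emulating the orientational averaging of a bulk solvent
# shell with a desk-scale number of molecules.
isotropic_triad_shell <- function(K = 6, r = 40, o = 5, seed = 1) {
  set.seed(seed)
  sites <- list(); id <- 1; molid <- 1
  for (k in seq_len(K)) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2)); R0 <- r * u
    a1 <- c(1, 0, 0); if (abs(sum(a1 * u)) > 0.9) a1 <- c(0, 1, 0)
    e1 <- a1 - sum(a1 * u) * u; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    offs <- lapply(0:2, function(m) o * (cos(2 * pi * m / 3) * e1 +
                                           sin(2 * pi * m / 3) * e2))
    axes <- list(u, e1, e2)
    for (m in 1:3) {
      C <- R0 + offs[[m]]; ax <- axes[[m]]
      pos <- rbind(C - 2.2 * ax, C, C + 2.2 * ax)
      sites[[length(sites) + 1]] <- data.frame(
        id = id:(id + 2), molecule = molid,
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        alpha = c(0.91, 5.93, 0.91))
      id <- id + 3; molid <- molid + 1
    }
  }
  pol_environment(sites = do.call(rbind, sites))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rotate_df <- function(df, Rm) {
  xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(Rm)
  df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
  df
}
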