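# Analytical gradients: contraction primitives, finite-difference agreement,
# conservation laws.

test_that("energy-weighted density satisfies its defining identities", {
  st <- run_rhf(mol_h2_sym(), options = tight_opts)
  W <- energy_weighted_density(st)
  # single doubly-occupied MO: W = 2 eps c c^T
  c1 <- st$C[, 1]
  expect_equal(unclass(W), 2 * st$eps[1] * tcrossprod(c1), tolerance = 1e-12)
  # Tr(W S) = 2 sum of occupied orbital energies
  st2 <- run_rhf(mol_h2o(), options = tight_opts)
  W2 <- energy_weighted_density(st2)
  expect_equal(sum(W2 * st2$system$S), 2 * sum(st2$eps[seq_len(st2$nocc)]),
               tolerance = 1e-10)
  # unconverged states are refused
  st_bad <- suppressWarnings(run_rhf(mol_h2o(), options = list(max_iter = 1)))
  expect_error(energy_weighted_density(st_bad), "not converged")
  expect_error(total_gradient(st_bad), "not converged")
})

test_that("field-integral derivative contraction matches per-integral finite differences", {
  mol <- mol_h2()
  env <- fixture_env(1, 0)
  sys <- build_system(mol, "sto-3g", env, scf_options())
  n <- length(sys$basis)
  # E = 0 gives zero
  g0 <- field_integral_derivative_contraction(sys, array(0, dim = dim(sys$Fe)))
  expect_equal(max(abs(g0)), 0)
  # single weight: derivative of one field integral
  E <- array(0, dim = dim(sys$Fe))
  E[2, 1, 2] <- E[2, 2, 1] <- 0.5   # weight 1 on the symmetric (1,2) pair
  g <- field_integral_derivative_contraction(sys, E)
  h <- 1e-5
  for (d in 1:3) {
    for (kind in list(c("site", 1), c("nucleus", 1))) {
      p <- displace(mol, env, kind[[1]], as.integer(kind[[2]]), d, h)
      Fp <- build_system(p$mol, "sto-3g", p$env, scf_options())$Fe[2, 1, 2]
      m <- displace(mol, env, kind[[1]], as.integer(kind[[2]]), d, -h)
      Fm <- build_system(m$mol, "sto-3g", m$env, scf_options())$Fe[2, 1, 2]
      row <- polembed:::particle_row(sys, kind[[1]], as.integer(kind[[2]]))
      expect_equal(g[row, d], (Fp - Fm) / (2 * h), tolerance = 1e-7)
    }
  }
  # translational invariance: columns of the full contraction sum to zero
  set.seed(51)
  E2 <- array(rnorm(length(sys$Fe)), dim = dim(sys$Fe))
  g2 <- field_integral_derivative_contraction(sys, E2)
  expect_lt(max(abs(colSums(g2))), 1e-10)
})

test_that("polarizability derivative contraction matches finite differences of A", {
  env <- fixture_env(2, 0)
  sys <- build_system(mol_h2_sym(), "sto-3g", env, scf_options())
  # single site: no T, zero contribution
  sys1 <- build_system(mol_h2_sym(), "sto-3g", fixture_env(1, 0), scf_options())
  gU <- polarizability_derivative_contraction(sys1, diag(3))
  expect_equal(max(abs(gU)), 0)

  set.seed(53)
  U <- matrix(rnorm(36), 6, 6)
  g <- polarizability_derivative_contraction(sys, U)
  h <- 1e-5
  for (d in 1:3) for (i in 1:2) {
    p <- displace(mol_h2_sym(), env, "site", i, d, h)
    Ap <- build_system(mol_h2_sym(), "sto-3g", p$env, scf_options())$A
    m <- displace(mol_h2_sym(), env, "site", i, d, -h)
    Am <- build_system(mol_h2_sym(), "sto-3g", m$env, scf_options())$A
    fd <- sum(((Ap - Am) / (2 * h)) * (U + t(U)) / 2)
    row <- polembed:::particle_row(sys, "site", i)
    expect_equal(g[row, d], fd, tolerance = 1e-7)
  }
})

test_that("J/K gradient corrections match finite differences of the contraction energies", {
  mol <- mol_h2()
  env <- fixture_env(2, 0)
  st <- run_rhf(mol, "sto-3g", env, tight_opts)
  sys <- st$system
  D <- st$D
  jk <- jk_gradient_corrections(sys, D, D)
  # zero densities
  jk0 <- jk_gradient_corrections(sys, D * 0, D * 0)
  expect_equal(max(abs(jk0$dJ)) + max(abs(jk0$dK)), 0)
  h <- 1e-5
  pt <- polembed:::particle_table(sys)
  for (r in c(1, 3, 4)) for (d in c(1, 3)) {
    ep <- em <- numeric(2)
    for (s in 1:2) {
      pp <- displace(mol, env, pt$kind[r], pt$index[r], d, c(h, -h)[s])
      s2 <- build_system(pp$mol, "sto-3g", pp$env, scf_options())
      dj <- delta_J(D, s2$Fe, s2$inter$AF)
      dk <- delta_K(D, s2$Fe, s2$inter$AF)
      ep[s] <- sum(D * dj)
      em[s] <- sum(D * dk)
    }
    expect_equal(jk$dJ[r, d], (ep[1] - ep[2]) / (2 * h), tolerance = 1e-6)
    expect_equal(jk$dK[r, d], (em[1] - em[2]) / (2 * h), tolerance = 1e-6)
  }
})

test_that("vacuum diatomic gradients are equal and opposite and follow the bond", {
  mol <- mol_h2_sym(1.3)
  st <- run_rhf(mol, options = tight_opts)
  g <- total_gradient(st)
  expect_equal(g$gradient[1, ], -g$gradient[2, ], tolerance = 1e-10)
  expect_lt(max(abs(g$gradient[, 1:2])), 1e-12)
  # compressed bond: moving atom 1 toward its partner raises the energy
  expect_gt(g$gradient[1, 3], 0)
})

test_that("analytical gradients match finite differences on embedded fixtures", {
  cases <- list(
    list(mol = mol_h2(), ns = 3, nc = 2, q = 0),
    list(mol = mol_heh(), ns = 1, nc = 2, q = 1))
  for (cfg in cases) {
    env <- fixture_env(cfg$ns, cfg$nc)
    opts <- c(tight_opts, list(charge = cfg$q))
    st <- run_rhf(cfg$mol, "sto-3g", env, opts)
    g <- total_gradient(st)
    pt <- g$particles
    for (r in seq_len(nrow(pt))) for (d in 1:3) {
      fd <- fd_energy_grad(cfg$mol, env, pt$kind[r], pt$index[r], d,
                           options = opts)
      # the gradient tolerance is absolute: 1e-6 hartree/bohr
      expect_lt(abs(g$gradient[r, d] - fd), 1e-6,
                label = paste("grad", pt$kind[r], r, "comp", d,
                              "|analytic - FD|"))
    }
    # conservation laws
    expect_lt(max(abs(colSums(g$gradient))), 1e-8)
    pos <- rbind(as.matrix(cfg$mol[, c("x", "y", "z")]),
                 as.matrix(env$charges[, c("x", "y", "z")]),
                 as.matrix(env$sites[, c("x", "y", "z")]))
    torque <- colSums(t(vapply(seq_len(nrow(pos)), function(i) {
      r <- pos[i, ]; f <- -g$gradient[i, ]
      c(r[2] * f[3] - r[3] * f[2], r[3] * f[1] - r[1] * f[3],
        r[1] * f[2] - r[2] * f[1])
    }, numeric(3))))
    expect_lt(max(abs(torque)), 1e-7)
  }
})

test_that("a zero-polarizability environment has the plain RHF + point-charge gradient", {
  mol <- mol_h2()
  env_q <- fixture_env(0, 2)
  env_q0 <- pol_environment(
    charges = env_q$charges,
    sites = data.frame(id = 50:51, x = c(1, -1), y = c(0, 1), z = c(2, -1),
                       alpha = c(0, 0)))
  st1 <- run_rhf(mol, "sto-3g", env_q, tight_opts)
  st2 <- run_rhf(mol, "sto-3g", env_q0, tight_opts)
  g1 <- total_gradient(st1)$gradient
  g2 <- total_gradient(st2)$gradient
  expect_equal(g1, g2, tolerance = 1e-12)
})
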