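# Basis handling and Gaussian integrals: parsing, normalization, core
# integrals and polarization integrals against the 3-D quadrature oracle.

test_that("Gaussian 94 basis text parses and unsupported content is rejected", {
  bs <- load_basis("sto-3g")
  expect_setequal(names(bs), c("H", "He", "C", "N", "O"))
  # SP shells split into S and P with shared exponents
  types <- vapply(bs$O, `[[`, "", "type")
  expect_equal(types, c("S", "S", "P"))
  expect_equal(bs$O[[2]]$exps, bs$O[[3]]$exps)
  expect_error(parse_basis_g94("Xx 0\nS 1 1.0\n1.0 1.0\n****"), "unknown element")
  expect_error(parse_basis_g94("H 0\nD 1 1.0\n1.0 1.0\n****"), "unsupported shell")
  expect_error(parse_basis_g94("H 0\nS 1 1.0\n-1.0 1.0\n****"), "exponents")
})

test_that("contracted AOs are normalized and S/T/V agree with quadrature", {
  b <- build_basis(mol_h2_sym(), "sto-3g")
  ints <- overlap_kinetic_nuclear(b, as.matrix(mol_h2_sym()[, c("x", "y", "z")]),
                                  c(1, 1))
  expect_equal(diag(ints$S), c(1, 1), tolerance = 1e-12)
  expect_equal(ints$S, t(ints$S))
  expect_gt(min(eigen(ints$S, only.values = TRUE)$values), 0)
  # quadrature oracle on every unique pair
  for (i in 1:2) for (j in i:2) {
    expect_equal(ints$S[i, j], polembed:::oracle_overlap(b[[i]], b[[j]]),
                 tolerance = 1e-8)
    expect_equal(ints$T[i, j], polembed:::oracle_kinetic(b[[i]], b[[j]]),
                 tolerance = 1e-8)
    v <- -polembed:::oracle_nuc(b[[i]], b[[j]], c(0, 0, 0)) -
      polembed:::oracle_nuc(b[[i]], b[[j]], c(0, 0, 1.4))
    expect_equal(ints$V[i, j], v, tolerance = 1e-8)
  }
})

test_that("duplicate basis functions are flagged as linearly dependent", {
  mol <- data.frame(element = c("H", "H"), x = 0, y = 0, z = 0)
  b <- build_basis(mol, "sto-3g")
  ints <- overlap_kinetic_nuclear(b, matrix(0, 1, 3), 2)
  expect_equal(ints$S[1, 2], 1, tolerance = 1e-12)
  expect_true(ints$linear_dependence)
})

test_that("electron repulsion integrals have 8-fold symmetry and match the layered oracle", {
  b <- build_basis(mol_h2_sym(), "sto-3g")
  eri <- electron_repulsion(b)
  expect_gt(eri[1, 1, 1, 1], 0)
  # permutational symmetry across a p-containing basis
  bo <- build_basis(data.frame(element = c("O", "H"), x = c(0, 0.4),
                               y = c(0, -0.3), z = c(0, 1.1)), "sto-3g")
  eo <- electron_repulsion(bo)
  set.seed(3)
  for (k in 1:25) {
    ix <- sample(seq_along(bo), 4, replace = TRUE)
    v <- eo[ix[1], ix[2], ix[3], ix[4]]
    expect_equal(eo[ix[2], ix[1], ix[3], ix[4]], v, tolerance = 1e-12)
    expect_equal(eo[ix[1], ix[2], ix[4], ix[3]], v, tolerance = 1e-12)
    expect_equal(eo[ix[3], ix[4], ix[1], ix[2]], v, tolerance = 1e-12)
  }
  # layered quadrature oracle: (mu nu|la si) = int rho_munu(r) Phi_lasi(r),
  # with the inner Coulomb potential from the (independently quadrature-
  # validated) one-electron path
  phi <- function(p) {
    vapply(seq_len(nrow(p)), function(k)
      polembed:::ao_pair_nuc(b[[1]], b[[2]], p[k, ]), 1.0)
  }
  v <- quadrature_oracle(function(p)
    polembed:::ao_value(b[[1]], p) * polembed:::ao_value(b[[2]], p) * phi(p),
    centers = rbind(b[[1]]$center, b[[2]]$center), scales = 1.5,
    tol = 1e-7)$value
  expect_equal(eri[1, 2, 1, 2], v, tolerance = 1e-6)
  expect_error(electron_repulsion(b, max_nao = 1), "refused")
})

test_that("damped field integrals obey symmetry limits and match quadrature", {
  # s.s pair centered at the site: odd integrand, zero field
  ao <- make_ao(c(0, 0, 0), c(0, 0, 0), c(0.8, 0.2), c(0.6, 0.5))
  sites <- data.frame(x = 0, y = 0, z = 0, alpha = 1.0, r0 = 1.0)
  Fe <- damped_field_integrals(list(ao), sites)
  expect_equal(as.vector(Fe), rep(0, 3), tolerance = 1e-14)

  # far-field multipole limit: component along the separation ~ S_munu / R^2
  R <- 20
  ao1 <- make_ao(c(0, 0, 0), c(0, 0, 0), 1.2)
  ao2 <- make_ao(c(0, 0, 0.8), c(0, 0, 0), 0.9)
  s12 <- polembed:::ao_pair_overlap(ao1, ao2)
  sites_far <- data.frame(x = 0, y = 0, z = -R + 0.4, alpha = 1, r0 = 1)
  Fe <- damped_field_integrals(list(ao1, ao2), sites_far)
  # charge centroid of the pair density sits at the Gaussian product center
  zc <- (1.2 * 0 + 0.9 * 0.8) / 2.1
  expect_equal(Fe[3, 1, 2], s12 / (zc - (-R + 0.4))^2, tolerance = 1e-6 * s12)
  expect_lt(abs(Fe[1, 1, 2]) + abs(Fe[2, 1, 2]), 1e-10)

  # randomized check against the 3-D oracle, s and p shells
  set.seed(17)
  for (k in 1:6) {
    A <- runif(3, -1, 1); B <- runif(3, -1, 1); Rs <- runif(3, -3, 3)
    pa <- sample(list(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), 1)[[1]]
    pb <- sample(list(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), 1)[[1]]
    a1 <- make_ao(A, pa, exp(runif(1, log(0.2), log(20))))
    a2 <- make_ao(B, pb, exp(runif(1, log(0.2), log(20))))
    r0 <- runif(1, 0.6, 1.5)
    v <- polembed:::contract_pair_vec(a1, a2, function(a, Ac, la, b, Bc, lb)
      polembed:::prim_field(a, Ac, la, b, Bc, lb, Rs, r0))
    o <- polembed:::oracle_field_multi(a1, a2, Rs, r0)
    expect_lt(max(abs(v - o)), 1e-8)
  }
})

test_that("CPP integrals are symmetric, PSD on the diagonal, and match quadrature", {
  set.seed(23)
  for (k in 1:4) {
    A <- runif(3, -1, 1); B <- runif(3, -1, 1); Rs <- runif(3, -2, 2)
    pa <- sample(list(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1)), 1)[[1]]
    a1 <- make_ao(A, pa, exp(runif(1, log(0.2), log(20))))
    a2 <- make_ao(B, c(0, 0, 0), exp(runif(1, log(0.2), log(20))))
    r0 <- runif(1, 0.6, 1.5)
    v <- polembed:::contract_pair_vec(a1, a2, function(a, Ac, la, b, Bc, lb)
      polembed:::prim_cpp(a, Ac, la, b, Bc, lb, Rs, r0))
    expect_equal(v, t(v), tolerance = 1e-14)
    o <- polembed:::oracle_cpp_multi(a1, a2, Rs, r0)
    expect_lt(max(abs(v - o)), 1e-8)
    # diagonal AO: integrand is a weighted outer product, 3x3 block PSD
    vd <- polembed:::contract_pair_vec(a1, a1, function(a, Ac, la, b, Bc, lb)
      polembed:::prim_cpp(a, Ac, la, b, Bc, lb, Rs, r0))
    expect_gt(min(eigen(vd, symmetric = TRUE, only.values = TRUE)$values),
              -1e-12)
  }
  # far-field limit: I ~ S * rhat rhat^T / R^4
  R <- 20
  ao1 <- make_ao(c(0, 0, 0), c(0, 0, 0), 1.1)
  ao2 <- make_ao(c(0, 0, 0.6), c(0, 0, 0), 1.3)
  s12 <- polembed:::ao_pair_overlap(ao1, ao2)
  v <- polembed:::contract_pair_vec(ao1, ao2, function(a, Ac, la, b, Bc, lb)
    polembed:::prim_cpp(a, Ac, la, b, Bc, lb, c(0, 0, -R), 1.0))
  zc <- (1.1 * 0 + 1.3 * 0.6) / 2.4
  expect_equal(v[3, 3], s12 / (zc + R)^4, tolerance = 1e-5 * s12)
})

test_that("nuclear field vectors use the shared damped kernel", {
  # single nucleus Z = 1 at distance r: C(r)/r^2 along the axis
  env <- pol_environment(sites = data.frame(id = 1, x = 0, y = 0, z = 0,
                                            alpha = 1))
  r <- 3.0
  f <- nuclear_field_vectors(matrix(c(0, 0, -r), 1, 3), 1, env)
  expect_equal(f, c(0, 0, field_damping(r, 1) / r^2), tolerance = 1e-12)

  # all charges excluded -> zero vector (QM nuclei absent)
  env2 <- pol_environment(charges = data.frame(id = 1, x = 0, y = 0, z = -2,
                                               q = 0.5),
                          sites = data.frame(id = 1, x = 0, y = 0, z = 0,
                                             alpha = 1))
  expect_equal(nuclear_field_vectors(NULL, numeric(0), env2), rep(0, 3))

  # neutral two-charge "molecule" far away ~ ideal point dipole to 1%
  d <- 0.5; R <- 30 * d
  env3 <- pol_environment(sites = data.frame(id = 9, x = 0, y = 0, z = 0,
                                             alpha = 1))
  f3 <- nuclear_field_vectors(matrix(c(0, 0, R + d / 2, 0, 0, R - d / 2),
                                     2, 3, byrow = TRUE), c(1, -1), env3)
  p_dip <- 1 * d   # dipole moment q*d pointing +z
  f_ideal <- 2 * p_dip / R^3   # on-axis point-dipole field, along +z
  expect_equal(f3[3], f_ideal, tolerance = 0.01)
  expect_equal(f3[1:2], c(0, 0))
})

test_that("fields of a neutral atom (point nucleus + matching density) nearly cancel", {
  # 1s^2-like density with 2 electrons exactly cancels Z = 2 outside
  he <- data.frame(element = "He", x = 0, y = 0, z = 0)
  st <- run_rhf(he, options = tight_opts)
  sys <- build_system(he, "sto-3g",
                      pol_environment(sites = data.frame(id = 1, x = 0, y = 0,
                                                         z = 8, alpha = 1)),
                      scf_options())
  f_elec <- as.vector(polembed:::fe_as_matrix(sys$Fe) %*% as.vector(st$D))
  f_nuc <- sys$Fn
  expect_gt(abs(f_nuc[3]), 1e-3)
  expect_lt(abs(f_elec[3] + f_nuc[3]), 1e-6 * abs(f_nuc[3]))
})

test_that("all integrals are invariant under global translation", {
  shift <- c(0.7, -1.3, 2.1)
  mol <- mol_h2()
  env <- fixture_env(2, 2)
  sys1 <- build_system(mol, "sto-3g", env, scf_options())
  mol2 <- mol; mol2$x <- mol2$x + shift[1]; mol2$y <- mol2$y + shift[2]
  mol2$z <- mol2$z + shift[3]
  env2 <- env
  for (cn in c("x", "y", "z")) {
    env2$charges[[cn]] <- env2$charges[[cn]] + shift[match(cn, c("x", "y", "z"))]
    env2$sites[[cn]] <- env2$sites[[cn]] + shift[match(cn, c("x", "y", "z"))]
  }
  sys2 <- build_system(mol2, "sto-3g", env2, scf_options())
  expect_equal(sys1$S, sys2$S, tolerance = 1e-12)
  expect_equal(sys1$T, sys2$T, tolerance = 1e-12)
  expect_equal(sys1$Vnuc, sys2$Vnuc, tolerance = 1e-9)
  expect_equal(sys1$eri, sys2$eri, tolerance = 1e-9)
  expect_equal(sys1$Fe, sys2$Fe, tolerance = 1e-9)
  expect_equal(sys1$Fn, sys2$Fn, tolerance = 1e-11)
  expect_equal(sys1$cpp, sys2$cpp, tolerance = 1e-9)
  expect_equal(sys1$H_pol, sys2$H_pol, tolerance = 1e-9)
  expect_equal(sys1$E0_pol, sys2$E0_pol, tolerance = 1e-13)
})

test_that("the quadrature oracle reproduces closed forms and reports failure", {
  ao <- make_ao(c(0.2, -0.1, 0.3), c(0, 0, 0), 0.9)
  # normalized s^2 integrates to 1
  r <- quadrature_oracle(function(p) polembed:::ao_value(ao, p)^2,
                         centers = ao$center, scales = 1)
  expect_equal(r$value, 1, tolerance = 1e-9)
  # overlap of two displaced primitives: Gaussian product theorem closed form
  a <- 0.8; b <- 1.3; d <- 1.1
  ao1 <- list(atom = 1L, center = c(0, 0, 0), pows = c(0L, 0L, 0L),
              exps = a, coefs = 1)
  ao2 <- list(atom = 1L, center = c(0, 0, d), pows = c(0L, 0L, 0L),
              exps = b, coefs = 1)
  closed <- exp(-a * b / (a + b) * d^2) * (pi / (a + b))^1.5
  r2 <- quadrature_oracle(function(p)
    polembed:::ao_value(ao1, p) * polembed:::ao_value(ao2, p),
    centers = rbind(ao1$center, ao2$center), scales = 1)
  expect_equal(r2$value, closed, tolerance = 1e-9)
  # field integral at a symmetric site is zero
  o <- polembed:::oracle_field_multi(ao, ao, ao$center, 1.0)
  expect_lt(max(abs(o)), 1e-9)
})
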