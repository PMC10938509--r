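# Classical interacting-induced-dipole model: dipole field tensor, effective
# polarizability, fields, energies, coarse-graining.

test_that("dipole field tensor reproduces the point-dipole kernel and its symmetries", {
  s <- data.frame(x = c(0, 0), y = c(0, 0), z = c(0, 2.5), alpha = c(1, 1))
  Tarr <- build_dipole_field_tensor(s, damping = "none")
  expect_equal(Tarr[, , 1, 2], diag(c(-1, -1, 2)) / 2.5^3, tolerance = 1e-14)
  # single site: no off-diagonal blocks, A = alpha * I
  A1 <- build_effective_polarizability(data.frame(x = 0, y = 0, z = 0,
                                                  alpha = 1.5))
  expect_equal(unclass(A1), diag(1.5, 3), tolerance = 1e-15)

  # random geometry: T^(ij) = T^(ji)^T and each block symmetric
  set.seed(11)
  s <- data.frame(x = rnorm(4), y = rnorm(4), z = rnorm(4),
                  alpha = runif(4, 0.5, 2))
  Tarr <- build_dipole_field_tensor(s)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(Tarr[, , i, j], t(Tarr[, , j, i]), tolerance = 1e-14)
    expect_equal(Tarr[, , i, j], t(Tarr[, , i, j]), tolerance = 1e-14)
  }
})

test_that("Thole damping keeps close-pair blocks finite and matches the r -> 0 limit", {
  a <- 2.1304
  s <- data.frame(x = c(0, 0), y = c(0, 0), z = c(0, 0.1), alpha = c(1, 1))
  Tarr <- build_dipole_field_tensor(s, damping = "thole", thole_a = a)
  expect_true(all(is.finite(Tarr)))
  # analytic r -> 0 limit of the damped kernel: T -> -(a/s)^3/6 * I
  lim <- -a^3 / 6   # (alpha_i alpha_j)^(1/6) = 1 here
  s0 <- data.frame(x = c(0, 0), y = c(0, 0), z = c(0, 1e-3), alpha = c(1, 1))
  T0 <- build_dipole_field_tensor(s0, damping = "thole", thole_a = a)
  expect_equal(T0[1, 1, 1, 2], lim, tolerance = 1e-2)
  expect_lt(max(abs(Tarr)), abs(lim) * 1.5)
  # coincident sites with damping disabled is a singular geometry
  sc <- data.frame(x = c(0, 0), y = c(0, 0), z = c(0, 0), alpha = c(1, 1))
  expect_error(build_dipole_field_tensor(sc, damping = "none"), "singular")
})

test_that("two-site Applequist response matches the closed form", {
  s <- data.frame(x = c(0, 0), y = c(0, 0), z = c(0, 10), alpha = c(1, 1))
  A <- build_effective_polarizability(s, damping = "none")
  f <- rep(c(0, 0, 1), 2)
  p <- induced_dipoles(A, f)
  expect_equal(p[3] + p[6], 2 / (1 - 2 / 1000), tolerance = 1e-13)
  # energy identity E = -1/2 f.p
  expect_equal(polarization_energy(A, f), -0.5 * sum(f * p), tolerance = 1e-14)
})

test_that("effective polarizability solves the coupled dipole equations on random fixtures", {
  set.seed(7)
  for (n in c(2, 5, 12, 20)) {
    s <- data.frame(x = runif(n, -6, 6), y = runif(n, -6, 6),
                    z = runif(n, -6, 6), alpha = runif(n, 0.4, 2))
    A <- build_effective_polarizability(s)
    expect_equal(unclass(A), t(unclass(A)), tolerance = 1e-12)
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)   # stable fixture: PSD
    f <- rnorm(3 * n)
    p <- induced_dipoles(A, f)
    p_direct <- solve_dipoles_direct(s, f)
    expect_lt(max(abs(p - p_direct)) / max(abs(p_direct)), 1e-10)
    expect_lte(polarization_energy(A, f), 0)
  }
})

test_that("polarization catastrophe is diagnosed with the offending pair", {
  s <- data.frame(x = c(0, 0), y = c(0, 0), z = c(0, 1.2), alpha = c(2, 2))
  # undamped: 2 alpha / r^3 > 1 makes the system unstable/singular near
  # the critical separation r = (2 alpha)^(1/3)
  expect_error(
    build_effective_polarizability(
      data.frame(x = c(0, 0), y = c(0, 0), z = c(0, (2 * 2)^(1 / 3)),
                 alpha = c(2, 2)), damping = "none"),
    "polarization catastrophe")
})

test_that("point-charge fields follow the sign convention and exclusions", {
  # positive charge below the site: field points up (charge -> site)
  env <- pol_environment(charges = data.frame(id = 1, x = 0, y = 0, z = -2,
                                              q = 1),
                         sites = data.frame(id = 2, x = 0, y = 0, z = 0,
                                            alpha = 1e-3))
  f <- point_charge_fields(env)
  expect_equal(f, c(0, 0, 0.25), tolerance = 1e-9)
  # same charge excluded (same id): zero field
  env2 <- pol_environment(charges = data.frame(id = 1, x = 0, y = 0, z = -2,
                                               q = 1),
                          sites = data.frame(id = 1, x = 0, y = 0, z = 0,
                                             alpha = 1e-3))
  expect_equal(point_charge_fields(env2), c(0, 0, 0))
  # two charges +/-1 symmetric about the site add with signs
  env3 <- pol_environment(charges = data.frame(id = 1:2, x = 0, y = 0,
                                               z = c(-2, 2), q = c(1, -1)),
                          sites = data.frame(id = 3, x = 0, y = 0, z = 0,
                                             alpha = 1e-3))
  expect_equal(point_charge_fields(env3), c(0, 0, 0.5), tolerance = 1e-9)
  # explicit exclusion pairs and 1-2/1-3 bonds
  env4 <- pol_environment(
    charges = data.frame(id = 1:3, x = c(0, 1, 2), y = 0, z = 0, q = 0.1),
    sites = data.frame(id = 4, x = 3, y = 0, z = 0, alpha = 1),
    bonds = data.frame(i = c(1, 2, 3), j = c(2, 3, 4)))
  # atoms 2 (1-3) and 3 (1-2) are excluded at site 4; only atom 1 acts
  expect_equal(sum(env4$excl), 2)
})

test_that("polarization energy is rotation invariant", {
  set.seed(21)
  s <- data.frame(x = runif(4, -3, 3), y = runif(4, -3, 3),
                  z = runif(4, -3, 3), alpha = runif(4, 0.5, 1.5))
  ch <- data.frame(id = 11:13, x = runif(3, 4, 7), y = runif(3, -6, -4),
                   z = runif(3, -2, 2), q = c(0.4, -0.2, -0.2))
  e0 <- local({
    env <- pol_environment(charges = ch, sites = cbind(id = 1:4, s))
    A <- build_effective_polarizability(env$sites)
    polarization_energy(A, point_charge_fields(env))
  })
  for (k in 1:5) {
    Rm <- random_rotation()
    env <- pol_environment(charges = rotate_df(ch, Rm),
                           sites = cbind(id = 1:4, rotate_df(s, Rm)))
    A <- build_effective_polarizability(env$sites)
    e <- polarization_energy(A, point_charge_fields(env))
    expect_equal(e, e0, tolerance = 1e-12)
  }
})

test_that("coarse-graining replaces only far molecules and is rotation invariant", {
  qm <- matrix(c(0, 0, 0), 1, 3)
  # near molecule untouched
  near <- data.frame(id = 1:3, molecule = 1, x = c(3, 4, 5), y = 0, z = 0,
                     alpha = c(0.9, 1.4, 0.9))
  env <- pol_environment(sites = near)
  cg <- coarse_grain(env, qm, cutoff = 10)
  expect_equal(nrow(cg$sites), 3)
  expect_equal(cg$sites$alpha, near$alpha)

  # far molecule collapsed to one site with the eigenvalue-mean polarizability
  far <- data.frame(id = 1:3, molecule = 1, x = c(30, 32, 34), y = 0, z = 0,
                    alpha = c(0.9, 1.4, 0.9))
  envf <- pol_environment(sites = far)
  cgf <- coarse_grain(envf, qm, cutoff = 10)
  expect_equal(nrow(cgf$sites), 1)
  expect_equal(cgf$sites$x, 32)   # atom closest to the centroid

  # the scalar coarse-grained polarizability is rotation invariant
  set.seed(5)
  alphas <- numeric(6)
  for (k in 1:6) {
    Rm <- if (k == 1) diag(3) else random_rotation()
    shifted <- far
    xyz <- as.matrix(far[, c("x", "y", "z")])
    ctr <- colMeans(xyz)
    xyz <- sweep(sweep(xyz, 2, ctr, "-") %*% t(Rm), 2, ctr + 5, "+")
    shifted$x <- xyz[, 1] + 20; shifted$y <- xyz[, 2]; shifted$z <- xyz[, 3]
    e2 <- pol_environment(sites = shifted)
    alphas[k] <- coarse_grain(e2, qm, cutoff = 10)$sites$alpha
  }
  expect_lt(max(abs(alphas - alphas[1])), 1e-10)

  # a one-atom molecule keeps its atomic alpha
  one <- data.frame(id = 1, molecule = 1, x = 40, y = 0, z = 0, alpha = 1.23)
  cg1 <- coarse_grain(pol_environment(sites = one), qm, cutoff = 10)
  expect_equal(cg1$sites$alpha, 1.23)
})

test_that("coarse-graining a far isotropic shell barely changes a test charge's polarization energy", {
  # ~9 molecular diameters away; orthogonal triads cancel the orientation
  # dependence that a single grained molecule cannot represent
  for (seed in 1:2) {
    env <- isotropic_triad_shell(seed = seed)
    env$charges <- tibble::tibble(id = 9999, molecule = 9999,
                                  x = 0, y = 0, z = 0, q = 1)
    env$excl <- matrix(FALSE, 1, nrow(env$sites))
    A <- build_effective_polarizability(env$sites, thole_a = env$thole_a)
    e_at <- polarization_energy(A, point_charge_fields(env))
    cg <- coarse_grain(env, matrix(0, 1, 3), cutoff = 10)
    expect_equal(nrow(cg$sites), max(env$sites$molecule))
    Acg <- build_effective_polarizability(cg$sites, thole_a = cg$thole_a)
    e_cg <- polarization_energy(Acg, point_charge_fields(cg))
    expect_lt(abs(e_cg - e_at) / abs(e_at), 0.01)
  }
})
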