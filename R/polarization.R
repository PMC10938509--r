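# Interacting induced-dipole model (Applequist with Thole damping):
# dipole field tensor, effective polarizability supermatrix, classical fields,
# induced dipoles, polarization energy, and coarse-graining of distant
# molecules.

#' Thole damping factors for the dipole field tensor
#'
#' Exponential-density damping: the interacting dipoles are smeared with an
#' exponentially decaying density of width `(alpha_i alpha_j)^(1/6) / a`,
#' which multiplies the 1/r^3 and 1/r^5 parts of the point-dipole tensor by
#' \deqn{\lambda_3 = 1 - e^{-x}(1 + x + x^2/2)}
#' \deqn{\lambda_5 = 1 - e^{-x}(1 + x + x^2/2 + x^3/6)}
#' with \eqn{x = a\, r / (\alpha_i\alpha_j)^{1/6}}. Both factors go to 1 at
#' long range and suppress the polarization catastrophe at short range.
#'
#' @param r Distance (bohr).
#' @param alpha_i,alpha_j Site polarizabilities (bohr^3).
#' @param a Thole constant.
#' @return List with `lambda3`, `lambda5`, and `x`.
#' @keywords internal
thole_lambdas <- function(r, alpha_i, alpha_j, a) {
  x <- a * r / (alpha_i * alpha_j)^(1 / 6)
  ex <- exp(-x)
  lambda3 <- 1 - ex * (1 + x + x^2 / 2)
  lambda5 <- 1 - ex * (1 + x + x^2 / 2 + x^3 / 6)
  list(lambda3 = lambda3, lambda5 = lambda5, x = x)
}

#' Build the dipole field tensor of a set of polarizable sites
#'
#' Returns all 3x3 blocks T^(ij) coupling point dipoles at sites i and j,
#' optionally Thole-damped. The undamped far-field block is the familiar
#' point-dipole kernel \eqn{(3\hat r\hat r^T - 1)/r^3}.
#'
#' @param sites Data frame with columns `x`, `y`, `z`, `alpha` (a
#'   `pol_environment` sites table works as-is), coordinates in bohr.
#' @param damping `"thole"` (default) or `"none"`.
#' @param thole_a Thole damping constant.
#' @return Array of dimension `(3, 3, n, n)` with class
#'   `dipole_field_tensor`; diagonal blocks are zero.
#' @export
build_dipole_field_tensor <- function(sites, damping = c("thole", "none"),
                                      thole_a = 2.1304) {
  damping <- match.arg(damping)
  n <- nrow(sites)
  if (n < 1) stop("need at least one polarizable site")
  R <- as.matrix(sites[, c("x", "y", "z")])
  alpha <- sites$alpha
  Tarr <- array(0, dim = c(3, 3, n, n))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- R[i, ] - R[j, ]
        r <- sqrt(sum(d * d))
        if (r < 1e-12 && damping == "none")
          stop("singular geometry: sites ", i, " and ", j,
               " coincide with damping disabled")
        if (damping == "thole") {
          lam <- thole_lambdas(r, alpha[i], alpha[j], thole_a)
          if (r < 1e-12) {
            # analytic r -> 0 limit: lambda3/r^3 -> (a/s)^3/6, lambda5 term -> 0
            s <- (alpha[i] * alpha[j])^(1 / 6) / thole_a
            blk <- -diag(3) / (6 * s^3)
          } else {
            rh <- d / r
            blk <- (3 * lam$lambda5 * tcrossprod(rh) - lam$lambda3 * diag(3)) / r^3
          }
        } else {
          rh <- d / r
          blk <- (3 * tcrossprod(rh) - diag(3)) / r^3
        }
        Tarr[, , i, j] <- blk
        Tarr[, , j, i] <- blk   # kernel symmetric in i <-> j (and blockwise)
      }
    }
  }
  structure(Tarr, class = "dipole_field_tensor",
            damping = damping, thole_a = thole_a)
}

# flatten the (3,3,n,n) block array into the 3n x 3n supermatrix
tensor_as_supermatrix <- function(Tarr) {
  n <- dim(Tarr)[3]
  M <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    M[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] <- Tarr[, , i, j]
  }
  M
}

#' Effective polarizability supermatrix of the MM system
#'
#' Solves the coupled Applequist equations: the 3n x 3n matrix `A` maps a
#' supervector of external fields at the sites to the self-consistent induced
#' dipoles, `p = A f`. In block form `A = (alpha^-1 - T)^-1`, factorized by
#' dense LU decomposition.
#'
#' @param sites Data frame with `x`, `y`, `z`, `alpha` (bohr / bohr^3).
#' @param tensor Optional precomputed [build_dipole_field_tensor()] result.
#' @inheritParams build_dipole_field_tensor
#' @return Symmetric `3n x 3n` matrix with class `effective_polarizability`.
#' @examples
#' s <- data.frame(x = 0, y = 0, z = 0, alpha = 1.5)
#' build_effective_polarizability(s)  # diag(1.5, 1.5, 1.5)
#' @export
build_effective_polarizability <- function(sites, tensor = NULL,
                                           damping = c("thole", "none"),
                                           thole_a = 2.1304) {
  damping <- match.arg(damping)
  n <- nrow(sites)
  if (n == 0) {
    return(structure(matrix(0, 0, 0), class = "effective_polarizability"))
  }
  if (any(sites$alpha <= 0))
    stop("all site polarizabilities must be > 0 (alpha = 0 sites are excluded upstream)")
  if (is.null(tensor)) tensor <- build_dipole_field_tensor(sites, damping, thole_a)
  M <- diag(rep(1 / sites$alpha, each = 3)) - tensor_as_supermatrix(tensor)
  rc <- rcond(M)
  if (!is.finite(rc) || rc < 1e-12) {
    # diagnose the offending pair: smallest damped separation
    R <- as.matrix(sites[, c("x", "y", "z")])
    dmin <- Inf; pair <- c(NA, NA)
    if (n > 1) {
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        r <- sqrt(sum((R[i, ] - R[j, ])^2))
        if (r < dmin) { dmin <- r; pair <- c(i, j) }
      }
    }
    stop("polarization catastrophe: dipole-interaction matrix is near singular",
         " (closest site pair ", pair[1], "-", pair[2],
         sprintf(", r = %.4f bohr)", dmin))
  }
  A <- solve(M)          # dense LU via LAPACK
  A <- (A + t(A)) / 2    # M is symmetric; remove roundoff asymmetry
  structure(A, class = "effective_polarizability")
}

#' Charge/field damping function C(r)
#'
#' Short-range cutoff applied to all charge-to-site and electron-to-site
#' fields and to the core polarization potentials:
#' \deqn{C(r) = (1 - e^{-(r/r_0)^2})^2.}
#' It vanishes quartically at the origin (regularizing every r^-k kernel used,
#' k <= 3 per power of C) and rises monotonically to 1. `r0` is tied to the
#' site polarizability, `r0 = field_c * alpha^(1/3)`.
#'
#' @param r Distance(s), bohr.
#' @param r0 Damping radius, bohr (> 0).
#' @return `C(r)` (and for [field_damping_deriv()] its derivative `dC/dr`).
#' @export
field_damping <- function(r, r0) {
  (1 - exp(-(r / r0)^2))^2
}

#' @rdname field_damping
#' @export
field_damping_deriv <- function(r, r0) {
  e <- exp(-(r / r0)^2)
  2 * (1 - e) * e * 2 * r / r0^2
}

#' Damped electric fields of the point charges at the polarizable sites
#'
#' \deqn{f^{(n)}_i = \sum_n Q_n\, C(|R_i - R_n|; r_{0,i})\,
#'   (R_i - R_n)/|R_i - R_n|^3}
#' with excluded charges omitted. The field of a positive charge points from
#' the charge toward the site. Only the MM charges of the environment enter
#' here; QM nuclei are added by [nuclear_field_vectors()].
#'
#' @param env A [pol_environment()].
#' @return Field supervector of length `3 * n_sites` (site-major: x, y, z of
#'   site 1, then site 2, ...).
#' @export
point_charge_fields <- function(env) {
  ns <- nrow(env$sites)
  f <- numeric(3 * ns)
  if (ns == 0 || nrow(env$charges) == 0) return(f)
  Rs <- site_positions(env)
  Rc <- charge_positions(env)
  for (i in seq_len(ns)) {
    d <- sweep(Rc, 2, Rs[i, ], "-")        # R_n - R_i
    r <- sqrt(rowSums(d * d))
    keep <- !env$excl[, i]
    if (any(keep & r < 1e-8))
      warning("charge coincident with polarizable site ", i,
              " and not excluded; damped field is finite but check the input")
    C <- field_damping(r, env$sites$r0[i])
    w <- ifelse(keep & r > 1e-300, env$charges$q * C / r^3, 0)
    f[(3 * i - 2):(3 * i)] <- -colSums(d * w)   # R_i - R_n direction
  }
  f
}

#' Induced dipoles from the effective polarizability
#'
#' `p = A f`: the self-consistent induced dipoles of all sites in response to
#' the total external field supervector.
#'
#' @param A Effective polarizability supermatrix.
#' @param f Field supervector (length `3 n`).
#' @return Dipole supervector (length `3 n`).
#' @export
induced_dipoles <- function(A, f) {
  stopifnot(length(f) == nrow(A))
  as.vector(A %*% f)
}

#' Classical polarization energy
#'
#' \deqn{E_{pol} = -\tfrac12 f^T A f = -\tfrac12 f \cdot p,}
#' non-positive whenever `A` is positive semidefinite (stable dipole system).
#'
#' @inheritParams induced_dipoles
#' @return Energy in hartree.
#' @export
polarization_energy <- function(A, f) {
  stopifnot(length(f) == nrow(A))
  -0.5 * sum(f * as.vector(A %*% f))
}

#' Coarse-grain distant polarizable molecules
#'
#' Any molecule whose atoms (charges and sites) all lie farther than `cutoff`
#' from every QM atom has its atomic polarizable sites replaced by a single
#' isotropic site. The molecular polarizability tensor is computed from the
#' molecule's own interacting-dipole system,
#' \eqn{\alpha^{\alpha\beta}_{mol} = \sum_{ij} A^{(mol)}_{i\alpha,j\beta}},
#' diagonalized, and the eigenvalue mean assigned as the scalar
#' polarizability. The combined site is placed on the site atom closest to the
#' molecule's geometric centre, and it keeps the molecule's own charges on its
#' exclusion list. Near molecules and all charges are untouched.
#'
#' @param env A [pol_environment()].
#' @param qm_atoms Matrix (n x 3) of QM atom positions in bohr (a molecule
#'   tibble with `x`,`y`,`z` also works).
#' @param cutoff Distance cutoff in bohr.
#' @return A new `pol_environment`.
#' @export
coarse_grain <- function(env, qm_atoms, cutoff) {
  stopifnot(cutoff > 0)
  if (is.data.frame(qm_atoms)) qm_atoms <- as.matrix(qm_atoms[, c("x", "y", "z")])
  qm_atoms <- matrix(qm_atoms, ncol = 3)
  if (nrow(env$sites) == 0) return(env)

  mols <- unique(c(env$sites$molecule, env$charges$molecule))
  new_sites <- list()
  new_excl_mol <- c()   # molecule label per new site row
  next_id <- max(c(env$charges$id, env$sites$id)) + 1

  for (m in mols) {
    s_idx <- which(env$sites$molecule == m)
    c_idx <- which(env$charges$molecule == m)
    pos <- rbind(site_positions(env)[s_idx, , drop = FALSE],
                 charge_positions(env)[c_idx, , drop = FALSE])
    if (length(s_idx) == 0) {
      if (length(c_idx) > 0 && nrow(env$sites) > 0) next  # charges-only molecule
      warning("molecule ", m, " has no polarizable atoms; skipped")
      next
    }
    dmin <- min(apply(qm_atoms, 1, function(q) {
      min(sqrt(rowSums(sweep(pos, 2, q, "-")^2)))
    }))
    if (dmin > cutoff && length(s_idx) >= 1) {
      sub <- env$sites[s_idx, , drop = FALSE]
      if (nrow(sub) == 1) {
        alpha_cg <- sub$alpha
        center_row <- 1
      } else {
        A_mol <- build_effective_polarizability(sub, damping = "thole",
                                                thole_a = env$thole_a)
        n <- nrow(sub)
        amol <- matrix(0, 3, 3)
        for (i in seq_len(n)) for (j in seq_len(n)) {
          amol <- amol + A_mol[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)]
        }
        alpha_cg <- mean(eigen((amol + t(amol)) / 2, symmetric = TRUE,
                               only.values = TRUE)$values)
        centroid <- colMeans(as.matrix(sub[, c("x", "y", "z")]))
        center_row <- which.min(rowSums(sweep(as.matrix(sub[, c("x", "y", "z")]),
                                              2, centroid, "-")^2))
      }
      new_sites[[length(new_sites) + 1]] <- tibble::tibble(
        id = next_id, molecule = m,
        x = sub$x[center_row], y = sub$y[center_row], z = sub$z[center_row],
        alpha = alpha_cg)
      new_excl_mol <- c(new_excl_mol, m)
      next_id <- next_id + 1
    } else {
      new_sites[[length(new_sites) + 1]] <-
        env$sites[s_idx, c("id", "molecule", "x", "y", "z", "alpha")]
      new_excl_mol <- c(new_excl_mol, rep(NA, length(s_idx)))
    }
  }
  sites2 <- do.call(rbind, new_sites)
  sites2$r0 <- env$field_c * sites2$alpha^(1 / 3)

  # rebuild the exclusion matrix: kept atomic sites inherit their old columns,
  # coarse-grained sites exclude their own molecule's charges
  excl2 <- matrix(FALSE, nrow(env$charges), nrow(sites2))
  for (k in seq_len(nrow(sites2))) {
    old <- match(sites2$id[k], env$sites$id)
    if (!is.na(old)) {
      excl2[, k] <- env$excl[, old]
    } else {
      excl2[, k] <- env$charges$molecule == sites2$molecule[k]
    }
  }

  out <- env
  out$sites <- tibble::as_tibble(sites2)
  out$excl <- excl2
  out
}
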