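# Synthetic solvent-shell fixtures: reproducible pseudo-random placement of
# rigid, apolar, polarizable 3-site "solvent" molecules around a QM region.
# The generator emulates the geometry statistics of an equilibrated apolar
# solvent shell (liquid-like number density, excluded volume, zero net charge
# per molecule, small bond charges, Applequist-style atomic polarizabilities)
# without running molecular dynamics.

#' Generate a synthetic apolar solvent shell
#'
#' Places `n_molecules` rigid linear 3-site molecules uniformly in a
#' spherical shell around the origin, rejection-sampled so that no atom comes
#' closer than `min_separation` to another molecule's atoms and no atom
#' enters the `qm_exclusion_radius` sphere reserved for the QM solute. Each
#' molecule carries small partial charges (+q on the two terminal sites,
#' -2q at the centre; net zero) and isotropic atomic polarizabilities, with
#' 1-2/1-3 bonded exclusions. The defaults mimic an apolar alkane-like
#' solvent: terminal charges of 0.0327 e, carbon-like polarizabilities, and
#' a toy-liquid number density.
#'
#' @param seed Integer seed; the fixture is a pure function of its arguments.
#' @param n_molecules Number of solvent molecules.
#' @param density Number density in molecules/bohr^3 (sets the outer shell
#'   radius).
#' @param qm_exclusion_radius Minimum distance of any solvent atom from the
#'   origin (bohr).
#' @param bond_length Intramolecular site spacing (bohr).
#' @param alpha Polarizabilities of the three sites (bohr^3).
#' @param q Terminal partial charge (elementary charges).
#' @param min_separation Minimum interatomic distance between molecules
#'   (bohr).
#' @param max_attempts Rejection-sampling guard per molecule.
#' @return A [pol_environment()] with molecule labels, bonds-derived
#'   exclusions and the default damping parameters.
#' @export
generate_solvent_shell <- function(seed, n_molecules, density = 1e-3,
                                   qm_exclusion_radius = 5.0,
                                   bond_length = 2.2,
                                   alpha = c(0.91, 5.93, 0.91),
                                   q = 0.0327,
                                   min_separation = 3.5,
                                   max_attempts = 2000) {
  stopifnot(n_molecules >= 0, density > 0, qm_exclusion_radius > 0)
  if (n_molecules == 0) return(pol_environment())
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  r_in <- qm_exclusion_radius + bond_length
  vol <- n_molecules / density
  r_out <- (3 * vol / (4 * pi) + r_in^3)^(1 / 3)

  atoms <- list()
  placed <- matrix(numeric(0), 0, 3)
  for (m in seq_len(n_molecules)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      # uniform in the shell volume
      u <- stats::runif(1)
      r <- ((r_out^3 - r_in^3) * u + r_in^3)^(1 / 3)
      ct <- stats::runif(1, -1, 1)
      ph <- stats::runif(1, 0, 2 * pi)
      st <- sqrt(1 - ct^2)
      center <- r * c(st * cos(ph), st * sin(ph), ct)
      # random orientation
      ax_ct <- stats::runif(1, -1, 1)
      ax_ph <- stats::runif(1, 0, 2 * pi)
      ax <- c(sqrt(1 - ax_ct^2) * cos(ax_ph), sqrt(1 - ax_ct^2) * sin(ax_ph), ax_ct)
      pos <- rbind(center - bond_length * ax, center, center + bond_length * ax)
      dmin_qm <- min(sqrt(rowSums(pos^2)))
      if (dmin_qm < qm_exclusion_radius) next
      if (nrow(placed) > 0) {
        dmin <- min(apply(pos, 1, function(p)
          min(sqrt(rowSums(sweep(placed, 2, p, "-")^2)))))
        if (dmin < min_separation) next
      }
      placed <- rbind(placed, pos)
      atoms[[m]] <- pos
      ok <- TRUE
      break
    }
    if (!ok)
      stop("packing failure: could not place molecule ", m, " after ",
           max_attempts, " attempts (density too high?)")
  }

  nm <- length(atoms)
  ids <- matrix(seq_len(3 * nm), ncol = 3, byrow = TRUE)
  charges <- do.call(rbind, lapply(seq_len(nm), function(m) {
    data.frame(id = ids[m, ], molecule = m,
               x = atoms[[m]][, 1], y = atoms[[m]][, 2], z = atoms[[m]][, 3],
               q = c(q, -2 * q, q))
  }))
  sites <- do.call(rbind, lapply(seq_len(nm), function(m) {
    data.frame(id = ids[m, ], molecule = m,
               x = atoms[[m]][, 1], y = atoms[[m]][, 2], z = atoms[[m]][, 3],
               alpha = alpha)
  }))
  bonds <- do.call(rbind, lapply(seq_len(nm), function(m) {
    data.frame(i = ids[m, c(1, 2)], j = ids[m, c(2, 3)])
  }))
  pol_environment(charges = charges, sites = sites, bonds = bonds)
}
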