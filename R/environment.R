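# The polarizable MM environment: point charges plus isotropic polarizable
# sites, with force-field style exclusion lists. This is the classical half of
# the direct reaction field model; the QM coupling lives in drf.R / scf.R.

#' Construct a polarizable MM environment
#'
#' The environment consists of fixed point charges and polarizable sites that
#' carry isotropic atomic dipole polarizabilities and develop induced dipoles
#' in response to electric fields. Charges and sites share one id space: an MM
#' atom that is both charged and polarizable appears in both tables under the
#' same id. A charge never acts on a site with the same id (self-field), and
#' 1-2 / 1-3 bonded neighbours are excluded when a bond list is supplied,
#' mirroring the exclusion lists of common force fields. Additional explicit
#' exclusions can be given as id pairs.
#'
#' Sites with exactly zero polarizability are dropped from the polarizable set
#' (the interacting-dipole equations presume invertible atomic
#' polarizabilities); their ids remain valid for exclusion bookkeeping.
#'
#' @param charges Data frame with columns `id`, `x`, `y`, `z`, `q` and
#'   optionally `molecule` (molecule membership label). May be `NULL` or empty.
#' @param sites Data frame with columns `id`, `x`, `y`, `z`, `alpha`
#'   (isotropic polarizability, bohr^3) and optionally `molecule`.
#' @param bonds Optional data frame with columns `i`, `j` of bonded atom id
#'   pairs; generates 1-2 and 1-3 exclusions.
#' @param exclusions Optional data frame with columns `charge_id`, `site_id`
#'   of explicit charge-to-site exclusions.
#' @param thole_a Dimensionless Thole damping constant for the dipole-dipole
#'   interaction (default 2.1304, the standard value for exponential-density
#'   damping).
#' @param field_c Proportionality constant linking the charge/electron-field
#'   damping radius to the site polarizability, `r0 = field_c * alpha^(1/3)`
#'   (bohr).
#' @param units Units of the input coordinates, `"bohr"` (default) or
#'   `"angstrom"`.
#' @return An object of class `pol_environment`: a list with tibbles
#'   `charges` and `sites` (coordinates in bohr, sites carry the damping
#'   radius `r0`), a logical exclusion matrix `excl` (charges x sites), and
#'   the damping parameters.
#' @examples
#' env <- pol_environment(
#'   charges = data.frame(id = 1, x = 0, y = 0, z = 0, q = 0.1),
#'   sites   = data.frame(id = 2, x = 0, y = 0, z = 3, alpha = 1.2)
#' )
#' env$sites$r0
#' @export
pol_environment <- function(charges = NULL, sites = NULL, bonds = NULL,
                            exclusions = NULL, thole_a = 2.1304,
                            field_c = 1.0, units = c("bohr", "angstrom")) {
  units <- match.arg(units)
  fac <- if (units == "angstrom") ANGSTROM_TO_BOHR else 1.0

  empty_charges <- tibble::tibble(id = integer(), molecule = integer(),
                                  x = numeric(), y = numeric(), z = numeric(),
                                  q = numeric())
  empty_sites <- tibble::tibble(id = integer(), molecule = integer(),
                                x = numeric(), y = numeric(), z = numeric(),
                                alpha = numeric(), r0 = numeric())

  if (is.null(charges) || nrow(charges) == 0) {
    charges <- empty_charges
  } else {
    need <- c("id", "x", "y", "z", "q")
    if (!all(need %in% names(charges)))
      stop("charges must have columns: ", paste(need, collapse = ", "))
    if (!("molecule" %in% names(charges))) charges$molecule <- charges$id
    charges <- tibble::as_tibble(charges[c("id", "molecule", "x", "y", "z", "q")])
    charges$x <- charges$x * fac
    charges$y <- charges$y * fac
    charges$z <- charges$z * fac
  }

  if (is.null(sites) || nrow(sites) == 0) {
    sites <- empty_sites
  } else {
    need <- c("id", "x", "y", "z", "alpha")
    if (!all(need %in% names(sites)))
      stop("sites must have columns: ", paste(need, collapse = ", "))
    if (any(sites$alpha < 0)) stop("site polarizabilities must be >= 0")
    if (!("molecule" %in% names(sites))) sites$molecule <- sites$id
    sites <- sites[sites$alpha > 0, , drop = FALSE]
    sites <- tibble::as_tibble(sites[c("id", "molecule", "x", "y", "z", "alpha")])
    sites$x <- sites$x * fac
    sites$y <- sites$y * fac
    sites$z <- sites$z * fac
    sites$r0 <- field_c * sites$alpha^(1 / 3)
  }

  excl <- matrix(FALSE, nrow(charges), nrow(sites))
  if (nrow(charges) > 0 && nrow(sites) > 0) {
    # self-exclusion: same atom id
    excl <- outer(charges$id, sites$id, `==`)
    pairs <- exclusion_pairs(bonds)
    if (!is.null(exclusions) && nrow(exclusions) > 0) {
      pairs <- rbind(pairs,
                     cbind(exclusions$charge_id, exclusions$site_id),
                     cbind(exclusions$site_id, exclusions$charge_id))
    }
    if (!is.null(pairs) && nrow(pairs) > 0) {
      key <- paste(pairs[, 1], pairs[, 2])
      grid <- outer(charges$id, sites$id, paste)
      excl <- excl | matrix(grid %in% key, nrow(charges), nrow(sites))
    }
  }

  structure(list(charges = charges, sites = sites, excl = excl,
                 thole_a = thole_a, field_c = field_c),
            class = "pol_environment")
}

# symmetric closure of 1-2 and 1-3 neighbour pairs from a bond list
exclusion_pairs <- function(bonds) {
  if (is.null(bonds) || nrow(bonds) == 0) return(NULL)
  b12 <- rbind(cbind(bonds$i, bonds$j), cbind(bonds$j, bonds$i))
  # 1-3: neighbours of neighbours
  nb <- split(b12[, 2], b12[, 1])
  b13 <- do.call(rbind, lapply(names(nb), function(a) {
    second <- unique(unlist(nb[as.character(nb[[a]])]))
    second <- second[second != as.numeric(a)]
    if (length(second) == 0) return(NULL)
    cbind(as.numeric(a), second)
  }))
  unique(rbind(b12, b13))
}

#' Update the damping parameters of an environment
#'
#' Replaces the Thole constant and/or the field-damping proportionality
#' constant, recomputing the per-site damping radii; exclusion lists are
#' preserved.
#'
#' @param env A [pol_environment()].
#' @param thole_a,field_c New values (`NULL` keeps the current one).
#' @return The updated environment.
#' @export
set_damping <- function(env, thole_a = NULL, field_c = NULL) {
  if (!is.null(thole_a)) env$thole_a <- thole_a
  if (!is.null(field_c)) env$field_c <- field_c
  if (nrow(env$sites) > 0) env$sites$r0 <- env$field_c * env$sites$alpha^(1 / 3)
  env
}

#' @export
print.pol_environment <- function(x, ...) {
  cat("<pol_environment> ", nrow(x$charges), " point charges, ",
      nrow(x$sites), " polarizable sites\n", sep = "")
  cat("  thole_a = ", x$thole_a, ", field_c = ", x$field_c,
      ", exclusions = ", sum(x$excl), "\n", sep = "")
  invisible(x)
}

site_positions <- function(env) {
  as.matrix(env$sites[, c("x", "y", "z")])
}

charge_positions <- function(env) {
  as.matrix(env$charges[, c("x", "y", "z")])
}
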