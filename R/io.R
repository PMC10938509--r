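# Plain-text input/output: XYZ geometries, YAML environment files, YAML run
# configurations, and JSON/TSV reports. External coordinates are Angstrom;
# everything internal is bohr.

#' Read an XYZ geometry file
#'
#' Standard XYZ: atom count, comment line, then `element x y z` records in
#' Angstrom. Returns coordinates in bohr.
#'
#' @param path File path.
#' @return Tibble with `element`, `x`, `y`, `z` (bohr).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("invalid XYZ file (line 1 must be the atom count): ", path)
  if (length(lines) < n + 2) stop("XYZ file truncated: ", path)
  rec <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  tibble::tibble(
    element = vapply(rec, `[`, "", 1),
    x = vapply(rec, function(r) as.numeric(r[2]), 1.0) * ANGSTROM_TO_BOHR,
    y = vapply(rec, function(r) as.numeric(r[3]), 1.0) * ANGSTROM_TO_BOHR,
    z = vapply(rec, function(r) as.numeric(r[4]), 1.0) * ANGSTROM_TO_BOHR)
}

#' Write an XYZ geometry file
#'
#' @param molecule Tibble with `element`, `x`, `y`, `z` in bohr.
#' @param path Output path.
#' @param comment Comment line.
#' @export
write_xyz <- function(molecule, path, comment = "") {
  lines <- c(nrow(molecule), comment,
             sprintf("%-2s %18.12f %18.12f %18.12f", molecule$element,
                     molecule$x / ANGSTROM_TO_BOHR,
                     molecule$y / ANGSTROM_TO_BOHR,
                     molecule$z / ANGSTROM_TO_BOHR))
  writeLines(lines, path)
}

.env_file_keys <- c("units", "charges", "sites", "bonds", "exclusions",
                    "thole_a", "field_c")

#' Read a polarizable-environment file
#'
#' YAML schema: optional `units` ("angstrom", the default, or "bohr"),
#' `charges` (list of records with `id`, `x`, `y`, `z`, `q` and optional
#' `molecule`), `sites` (records with `id`, `x`, `y`, `z`, `alpha`, optional
#' `molecule`), optional `bonds` (records `i`, `j`), optional `exclusions`
#' (records `charge_id`, `site_id`), and optional damping parameters
#' `thole_a`, `field_c`. Unknown keys are rejected.
#'
#' @param path File path.
#' @return A [pol_environment()].
#' @export
read_environment <- function(path) {
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), .env_file_keys)
  if (length(unknown) > 0)
    stop("unknown key(s) in environment file ", path, ": ",
         paste(unknown, collapse = ", "))
  as_df <- function(x) if (is.null(x)) NULL else
    do.call(rbind.data.frame, lapply(x, as.data.frame))
  pol_environment(
    charges = as_df(y$charges), sites = as_df(y$sites),
    bonds = as_df(y$bonds), exclusions = as_df(y$exclusions),
    thole_a = if (is.null(y$thole_a)) 2.1304 else y$thole_a,
    field_c = if (is.null(y$field_c)) 1.0 else y$field_c,
    units = if (is.null(y$units)) "angstrom" else y$units)
}

#' Write a polarizable-environment file
#'
#' Inverse of [read_environment()]; coordinates are written in Angstrom.
#' Exclusions are exported explicitly (the bond list is not reconstructed).
#'
#' @param env A [pol_environment()].
#' @param path Output path.
#' @export
write_environment <- function(env, path) {
  to_recs <- function(df, cols) {
    lapply(seq_len(nrow(df)), function(i) {
      r <- as.list(df[i, cols])
      for (k in c("x", "y", "z")) r[[k]] <- r[[k]] / ANGSTROM_TO_BOHR
      r
    })
  }
  excl <- NULL
  if (length(env$excl) && any(env$excl)) {
    w <- which(env$excl, arr.ind = TRUE)
    keep <- env$charges$id[w[, 1]] != env$sites$id[w[, 2]]
    if (any(keep)) {
      excl <- lapply(which(keep), function(k)
        list(charge_id = env$charges$id[w[k, 1]],
             site_id = env$sites$id[w[k, 2]]))
    }
  }
  y <- list(units = "angstrom",
            thole_a = env$thole_a, field_c = env$field_c,
            charges = to_recs(env$charges, c("id", "molecule", "x", "y", "z", "q")),
            sites = to_recs(env$sites, c("id", "molecule", "x", "y", "z", "alpha")),
            exclusions = excl)
  y <- y[!vapply(y, is.null, TRUE)]
  yaml::write_yaml(y, path, precision = 15)
}

.config_keys <- c("geometry", "environment", "basis", "mode",
                  "coarse_grain_cutoff", "damping", "ri_mode", "scf", "seed",
                  "output")
.scf_keys <- c("max_iter", "conv_commutator", "conv_energy", "charge",
               "diis", "include_mm_coulomb")

#' Parse and validate a run configuration
#'
#' Reads a YAML run configuration, validates it against the strict schema
#' (unknown keys rejected with the offending key named), resolves file paths
#' relative to the configuration file, loads geometry/environment/basis, and
#' applies coarse-graining when `coarse_grain_cutoff` (Angstrom) is set.
#'
#' Recognised keys: `geometry` (XYZ path, required), `environment` (YAML
#' path), `basis` (name or path, default "sto-3g"), `mode` ("energy",
#' "gradient" or "polarization-report"), `coarse_grain_cutoff` (Angstrom),
#' `damping` (`thole_a`, `field_c`), `ri_mode`, `scf`
#' (`max_iter`, `conv_commutator`, `conv_energy`, `charge`, `diis`,
#' `include_mm_coulomb`), `seed`, `output`.
#'
#' @param path Configuration file path.
#' @param overrides Named list applied on top of the file contents (used by
#'   the command line flags).
#' @return Validated run description: `molecule`, `environment`, `basis`,
#'   `mode`, `options`, `seed`, `output`, `config`.
#' @export
parse_inputs <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  y <- modifyList(y, overrides)
  unknown <- setdiff(names(y), .config_keys)
  if (length(unknown) > 0)
    stop("unknown key(s) in config ", path, ": ",
         paste(unknown, collapse = ", "))
  if (is.null(y$geometry)) stop("config must name a 'geometry' XYZ file")
  if (!is.null(y$scf)) {
    bad <- setdiff(names(y$scf), .scf_keys)
    if (length(bad) > 0)
      stop("unknown scf option(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(y$damping)) {
    bad <- setdiff(names(y$damping), c("thole_a", "field_c"))
    if (length(bad) > 0)
      stop("unknown damping option(s): ", paste(bad, collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  mode <- if (is.null(y$mode)) "energy" else y$mode
  if (!(mode %in% c("energy", "gradient", "polarization-report")))
    stop("unknown mode: ", mode)
  molecule <- read_xyz(resolve(y$geometry))
  env <- if (!is.null(y$environment)) read_environment(resolve(y$environment))
         else pol_environment()
  if (!is.null(y$damping)) {
    env <- set_damping(env, thole_a = y$damping$thole_a,
                       field_c = y$damping$field_c)
  }
  if (!is.null(y$coarse_grain_cutoff)) {
    env <- coarse_grain(env, as.matrix(molecule[, c("x", "y", "z")]),
                        y$coarse_grain_cutoff * ANGSTROM_TO_BOHR)
  }
  opts <- scf_options()
  if (!is.null(y$scf)) opts <- modifyList(opts, y$scf)
  if (!is.null(y$ri_mode)) opts$ri_mode <- y$ri_mode
  list(molecule = molecule, environment = env,
       basis = if (is.null(y$basis)) "sto-3g" else resolve_basis_name(y$basis, base),
       mode = mode, options = opts,
       seed = if (is.null(y$seed)) 1L else as.integer(y$seed),
       output = y$output, config = y)
}

resolve_basis_name <- function(basis, base) {
  if (tolower(basis) %in% c("sto-3g", "sto3g")) return("sto-3g")
  if (file.exists(basis)) basis else file.path(base, basis)
}

#' Write a JSON run report
#'
#' Energy decomposition, per-site induced dipoles, convergence trace, and an
#' optional gradient block. All numbers at full precision; the timestamp is
#' isolated in a single field so reports are otherwise byte-reproducible.
#'
#' @param state [run_rhf()] state.
#' @param path Output path (JSON).
#' @param gradient Optional [total_gradient()] report.
#' @param timestamp Timestamp string; pass `""` for reproducible output.
#' @export
write_report <- function(state, path, gradient = NULL,
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  mf <- state_polarization(state)
  rep <- list(
    timestamp = timestamp,
    E_total = state$E_total,
    converged = state$converged,
    n_iter = state$n_iter,
    E_components = as.list(state$E_components),
    E_pol_state = mf$E_pol_state,
    orbital_energies = state$eps,
    induced_dipoles = if (nrow(mf$sites) > 0) mf$sites else NULL,
    convergence = state$trace
  )
  if (!is.null(gradient)) {
    rep$gradient <- gradient$particles
    rep$net_force <- colSums(gradient$gradient)
  }
  rep <- rep[!vapply(rep, is.null, TRUE)]
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write the induced-dipole table
#'
#' Plain TSV export (site id, position, dipole vector, norm) of the
#' state-dependent induced dipoles — the tabular counterpart of a dipole-
#' visualization plot.
#'
#' @param state [run_rhf()] state.
#' @param path Output path (TSV).
#' @export
write_dipole_table <- function(state, path) {
  mf <- state_polarization(state)
  utils::write.table(mf$sites, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
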