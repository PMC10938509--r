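# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy an SCF state
#'
#' One row per molecular orbital: index, energy (hartree), occupation.
#'
#' @param x [run_rhf()] result.
#' @param ... Unused.
#' @return Tibble with `orbital`, `energy`, `occupation`.
#' @method tidy scf_state
#' @export
tidy.scf_state <- function(x, ...) {
  tibble::tibble(orbital = seq_along(x$eps), energy = x$eps,
                 occupation = ifelse(seq_along(x$eps) <= x$nocc, 2, 0))
}

#' Glance at an SCF state
#'
#' One-row summary: total energy, convergence, iteration count, environment
#' size, the zero-electron reaction field constant and the state polarization
#' energy.
#'
#' @inheritParams tidy.scf_state
#' @return One-row tibble.
#' @method glance scf_state
#' @export
glance.scf_state <- function(x, ...) {
  mf <- state_polarization(x)
  tibble::tibble(
    E_total = x$E_total, converged = x$converged, n_iter = x$n_iter,
    n_ao = length(x$eps), n_sites = nrow(x$system$env$sites),
    n_charges = nrow(x$system$env$charges),
    E0_pol = x$system$E0_pol, E_pol_state = mf$E_pol_state)
}

#' @rdname tidy.scf_state
#' @method tidy gradient_report
#' @export
tidy.gradient_report <- function(x, ...) {
  out <- x$particles
  out$g_norm <- sqrt(out$gx^2 + out$gy^2 + out$gz^2)
  out
}

#' @rdname tidy.scf_state
#' @method tidy mean_field_response
#' @export
tidy.mean_field_response <- function(x, ...) {
  x$sites
}

#' Convergence-trace plot of an SCF run
#'
#' Energy error (relative to the final energy) and the commutator norm per
#' iteration on a log scale.
#'
#' @param object [run_rhf()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scf_state
#' @export
autoplot.scf_state <- function(object, ...) {
  tr <- object$trace
  tr$dE <- abs(tr$energy - object$E_total)
  df <- rbind(
    data.frame(iter = tr$iter, value = pmax(tr$dE, 1e-16),
               quantity = "|E - E_final|"),
    data.frame(iter = tr$iter, value = pmax(tr$error, 1e-16),
               quantity = "max |FDS - SDF|"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iter, y = .data$value,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "SCF iteration", y = "hartree / a.u.",
                  title = "SCF convergence") +
    ggplot2::theme_minimal()
}

#' Induced-dipole plot of a mean-field response
#'
#' Dipole magnitude of every polarizable site against its distance from a
#' reference point (default: origin of the QM frame).
#'
#' @param object [state_polarization()] result.
#' @param origin Reference point (bohr).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mean_field_response
#' @export
autoplot.mean_field_response <- function(object, origin = c(0, 0, 0), ...) {
  s <- object$sites
  s$distance <- sqrt((s$x - origin[1])^2 + (s$y - origin[2])^2 +
                       (s$z - origin[3])^2)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$distance, y = .data$p_norm)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "distance from QM region (bohr)",
                  y = "|induced dipole| (e bohr)",
                  title = "State-dependent induced dipoles") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
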