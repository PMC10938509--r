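# Small numerical utilities shared by the integral and polarization code.

#' Unit conversion: Angstrom to bohr
#'
#' CODATA conversion factor used everywhere coordinates cross the package
#' boundary. All internal arithmetic is in hartree atomic units
#' (bohr / hartree / elementary charge).
#'
#' @format Length-one numeric.
#' @export
ANGSTROM_TO_BOHR <- 1.8897261254578281

#' Gauss-Legendre nodes and weights on an interval
#'
#' Golub-Welsch: nodes are eigenvalues of the symmetric tridiagonal Jacobi
#' matrix of the Legendre recurrence; weights follow from the first component
#' of the eigenvectors.
#'
#' @param n Number of nodes.
#' @param a,b Interval endpoints (default \code{[-1, 1]}).
#' @return List with numeric vectors `nodes` and `weights`.
#' @keywords internal
gauss_legendre <- function(n, a = -1, b = 1) {
  stopifnot(n >= 1)
  if (n == 1) {
    x <- 0
    w <- 2
  } else {
    k <- seq_len(n - 1)
    beta <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(k, k + 1)] <- beta
    J[cbind(k + 1, k)] <- beta
    e <- eigen(J, symmetric = TRUE)
    x <- e$values
    w <- 2 * e$vectors[1, ]^2
    o <- order(x)
    x <- x[o]
    w <- w[o]
  }
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

# cache for repeated rule requests
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre_cached <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) .gl_cache[[key]] <- gauss_legendre(n)
  .gl_cache[[key]]
}

#' Boys function F_n(x)
#'
#' \deqn{F_n(x) = \int_0^1 t^{2n} e^{-x t^2} dt}
#' evaluated through the regularized lower incomplete gamma function
#' (`pgamma`), with the Taylor limit for very small arguments. Returns the
#' whole ladder 0..nmax, which the Hermite-Coulomb recursion consumes.
#'
#' @param nmax Highest order needed.
#' @param x Argument (scalar, >= 0).
#' @return Numeric vector of length `nmax + 1`: F_0(x) .. F_nmax(x).
#' @keywords internal
boys <- function(nmax, x) {
  n <- 0:nmax
  if (x < 1e-13) {
    return(1 / (2 * n + 1) - x / (2 * n + 3))
  }
  # F_n(x) = Gamma(n+1/2) P(n+1/2, x) / (2 x^(n+1/2))
  a <- n + 0.5
  gamma(a) * stats::pgamma(x, a) / (2 * x^a)
}

# double factorial (n odd or even, n >= -1)
double_factorial <- function(n) {
  if (n <= 0) return(1)
  prod(seq(n, 1, by = -2))
}

# Gaussian moment  int_-inf^inf  u^n exp(-q u^2) du  (vectorised over q)
gaussian_moment_1d <- function(n, q) {
  if (n %% 2 == 1) return(rep(0, length(q)))
  double_factorial(n - 1) / (2 * q)^(n / 2) * sqrt(pi / q)
}
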