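# Gaussian basis handling: "Gaussian 94"-style basis text parsing, a bundled
# minimal (STO-3G) basis for H, He, C, N, O, and construction of contracted
# Cartesian atomic orbitals. Only s and p shells are supported; the AO order
# within a p shell is Cartesian x, y, z.

ELEMENT_Z <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
               F = 9, Ne = 10)

#' Parse a Gaussian 94 style basis set text block
#'
#' Accepts the plain-text dialect used by basis-set exchanges: element header
#' lines (`H     0`), shell headers (`S   3   1.00` or `SP  3   1.00`),
#' primitive lines of exponent + contraction coefficient(s), and `****`
#' separators. Fortran `D` exponents are accepted. Only S, P and SP shells
#' are supported.
#'
#' @param text Character vector of lines, or a single string with newlines.
#' @return Named list (by element symbol) of shells; each shell is a list
#'   with `type` ("S" or "P"), `exps`, `coefs`.
#' @export
parse_basis_g94 <- function(text) {
  if (length(text) == 1 && grepl("\n", text)) {
    text <- strsplit(text, "\n")[[1]]
  }
  lines <- trimws(text)
  lines <- lines[lines != "" & !grepl("^!", lines)]
  out <- list()
  i <- 1
  n <- length(lines)
  num <- function(x) as.numeric(gsub("[dD]", "e", x))
  while (i <= n) {
    if (grepl("^\\*+$", lines[i])) { i <- i + 1; next }
    hdr <- strsplit(lines[i], "\\s+")[[1]]
    elem <- hdr[1]
    if (!(elem %in% names(ELEMENT_Z)))
      stop("unknown element in basis text: ", elem)
    i <- i + 1
    shells <- list()
    while (i <= n && !grepl("^\\*+$", lines[i])) {
      sh <- strsplit(lines[i], "\\s+")[[1]]
      type <- toupper(sh[1])
      nprim <- as.integer(sh[2])
      if (!(type %in% c("S", "P", "SP")))
        stop("unsupported shell type '", type, "' (only s and p shells)")
      i <- i + 1
      rows <- do.call(rbind, lapply(lines[i:(i + nprim - 1)], function(l) {
        num(strsplit(l, "\\s+")[[1]])
      }))
      i <- i + nprim
      if (any(rows[, 1] <= 0)) stop("primitive exponents must be > 0")
      if (type == "SP") {
        shells <- c(shells,
                    list(list(type = "S", exps = rows[, 1], coefs = rows[, 2])),
                    list(list(type = "P", exps = rows[, 1], coefs = rows[, 3])))
      } else {
        shells <- c(shells,
                    list(list(type = type, exps = rows[, 1], coefs = rows[, 2])))
      }
    }
    out[[elem]] <- shells
  }
  out
}

#' Load a bundled or external basis set
#'
#' `"sto-3g"` resolves to the bundled minimal basis (H, He, C, N, O); any
#' other value is treated as a path to a Gaussian 94 style text file.
#'
#' @param name Basis name or file path.
#' @return Parsed basis list as from [parse_basis_g94()].
#' @export
load_basis <- function(name = "sto-3g") {
  if (tolower(name) %in% c("sto-3g", "sto3g")) {
    path <- system.file("extdata", "sto-3g.g94", package = "polembed")
    if (path == "") path <- file.path("inst", "extdata", "sto-3g.g94")
  } else {
    path <- name
  }
  if (!file.exists(path)) stop("basis file not found: ", path)
  parse_basis_g94(readLines(path))
}

# normalization constant of a primitive Cartesian Gaussian x^i y^j z^k e^{-a r^2}
prim_norm <- function(a, pows) {
  l <- sum(pows)
  (2 * a / pi)^0.75 * (4 * a)^(l / 2) /
    sqrt(prod(vapply(pows, function(k) double_factorial(2 * k - 1), 1.0)))
}

#' Build the contracted AO basis for a molecule
#'
#' @param molecule Data frame with columns `element`, `x`, `y`, `z`
#'   (coordinates in bohr) as produced by [read_xyz()].
#' @param basis Parsed basis set ([load_basis()]) or a basis name.
#' @return List of class `ao_basis`: one entry per contracted Cartesian AO
#'   with fields `atom`, `center`, `pows`, `exps`, `coefs` (contraction
#'   coefficients times primitive norms, rescaled so that <mu|mu> = 1),
#'   and `label`.
#' @export
build_basis <- function(molecule, basis = "sto-3g") {
  if (is.character(basis)) basis <- load_basis(basis)
  aos <- list()
  for (ia in seq_len(nrow(molecule))) {
    el <- molecule$element[ia]
    if (is.null(basis[[el]]))
      stop("basis has no entry for element ", el)
    center <- c(molecule$x[ia], molecule$y[ia], molecule$z[ia])
    for (sh in basis[[el]]) {
      pow_list <- if (sh$type == "S") list(c(0L, 0L, 0L))
                  else list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
      for (pows in pow_list) {
        comp <- if (sum(pows) == 0) "s" else c("px", "py", "pz")[which(pows == 1L)]
        coefs <- sh$coefs * vapply(sh$exps, prim_norm, 1.0, pows = pows)
        ao <- list(atom = ia, center = center, pows = pows,
                   exps = sh$exps, coefs = coefs,
                   label = paste0(el, ia, "_", comp))
        # normalize the contraction
        s <- ao_pair_overlap(ao, ao)
        ao$coefs <- ao$coefs / sqrt(s)
        aos[[length(aos) + 1]] <- ao
      }
    }
  }
  structure(aos, class = "ao_basis")
}

#' @export
print.ao_basis <- function(x, ...) {
  cat("<ao_basis> ", length(x), " contracted Cartesian AOs (s/p)\n", sep = "")
  invisible(x)
}

# shift the angular momentum of an AO in one Cartesian dimension; used by the
# center-derivative (raising/lowering) machinery. Keeps coefficients as-is.
ao_shift <- function(ao, dim, by) {
  ao$pows[dim] <- ao$pows[dim] + by
  stopifnot(ao$pows[dim] >= 0)
  ao
}
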