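---
title: "Direct reaction field embedding in polembed: model, numerics, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct reaction field embedding in polembed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
physical model and its assumptions, every tunable parameter that matters, the
numerical choices, what the synthetic fixtures do and do not emulate, and the
known limitations.

## The model

A system is split into a QM solute (nuclei plus electrons, treated at the
restricted Hartree–Fock level over contracted s/p Gaussian bases) and an MM
environment of point charges $Q_n$ and polarizable sites with isotropic
atomic polarizabilities $\alpha_i$ (bohr$^3$). The sites carry induced point
dipoles that interact with each other through the dipole field tensor and
respond to all charges — classical and electronic alike.

**Classical half.** Eliminating the coupled induced dipoles exactly gives
the effective polarizability supermatrix
$A = (\boldsymbol\alpha^{-1} - T)^{-1}$ (dense, $3N_{pol}\times3N_{pol}$,
factorized by LU decomposition once per geometry), so that $p = A f$ for any
field supervector and the classical polarization energy is
$-\tfrac12 f^T A f$. The dipole–dipole kernel is Thole-damped
(exponential-density form):
$T_{\gamma\delta} = (3\lambda_5 \hat r_\gamma \hat r_\delta - \lambda_3
\delta_{\gamma\delta})/r^3$ with
$\lambda_3 = 1 - e^{-x}(1 + x + x^2/2)$,
$\lambda_5 = 1 - e^{-x}(1 + x + x^2/2 + x^3/6)$, and
$x = a\, r/(\alpha_i\alpha_j)^{1/6}$. This suppresses the polarization
catastrophe; the undamped kernel is available (`damping = "none"`) and is
used wherever a closed form is being checked.

**Quantum coupling.** The polarization energy operator
$-\tfrac12 \hat f^T A \hat f$ is expanded by electron count into the
two-electron tensor
$(\mu\nu|\lambda\sigma)_{pol} = -F^{(e)T}_{\mu\nu} A F^{(e)}_{\lambda\sigma}$,
a one-electron correction, and the zero-electron constant
$-\tfrac12 F^{(n)T} A F^{(n)}$. The sign bookkeeping is fixed once:
$F^{(e)}_{i\alpha,\mu\nu}$ is the matrix element of the *electron's* field
(charge included), and the field of a positive charge points from the charge
toward the site. Rather than trusting any transcription of these
conventions, the package pins them down operationally with two oracles that
run in the test suite: the converged SCF energy must equal the term-by-term
trace assembly to 1e-10, and every analytical gradient component must match
central finite differences of the total energy to 1e-6 hartree/bohr.

The electron self-interaction through the sites couples two field operators
of the same electron. Cross-site terms are split by a resolution of the
identity (RI) over the primary basis — the inverse overlap, replaced by a
pseudoinverse (singular values below $10^{-8}$ of the largest dropped) when
the basis is linearly dependent. Same-site terms are kept exact by default:
they reduce to core-polarization-potential (CPP) integrals with the kernel
$C^2(r)\, r_\alpha r_\beta / r^6$ weighted by the diagonal $3\times3$ blocks
of $A$ (`ri_mode = "exact-same-site"`); `"pure-ri"` treats everything on the
RI footing.

**State-dependent response.** After convergence, the expectation fields
$f = F^{(n)} + \sum_{\mu\nu} D_{\mu\nu} F^{(e)}_{\mu\nu}$ give the induced
dipoles $p = A f$ and the mean-field polarization energy
$-\tfrac12 f^T A f$ (`state_polarization()`). These are diagnostics: the
energetics enter through the Hamiltonian, identically for every state.

## Damping of the charge/electron fields

All charge-to-site and electron-to-site kernels share one damping function

$$C(r) = \left(1 - e^{-(r/r_0)^2}\right)^2, \qquad r_0 = c\,\alpha^{1/3},$$

with `field_c` $c = 1$ by default. $C$ vanishes quartically at the origin —
enough zeros to regularize every $r^{-k}$ kernel used (the CPP integral does
not exist without it) — and rises monotonically to 1. Using the *same* $C$
for electronic and nuclear fields makes the net field of a neutral atom
(point nucleus plus matching electron density) cancel outside the density,
which the suite asserts to 1e-6 relative. The damping radius is tied to the
site polarizability because more polarizable atoms are bigger; the
proportionality constant is exposed because it is a modeling choice, not
physics.

## Integral evaluation

Two independent routes exist for every integral; their agreement is an
acceptance criterion.

*Default (analytic) path.* Overlap, kinetic, nuclear-attraction and
electron-repulsion integrals use McMurchie–Davidson Hermite expansions with
Boys functions (evaluated through the regularized incomplete gamma). For the
damped field integrals, $C(r)$ expands into three Gaussian terms
($1 - 2e^{-br^2} + e^{-2br^2}$), each of which recombines with the orbital
pair into a single Gaussian, reducing the integral to Hermite–Coulomb
derivative tables — closed form up to the Boys function. The CPP kernel
cannot be split that way (its undamped piece diverges), so $r^{-6}$ is
written as a one-dimensional Gaussian transform,
$r^{-6} = \int_0^\infty t^5 e^{-r^2 t^2}\,dt$, the damping sum is kept
inside, and the inner three-dimensional integral becomes pure Gaussian
moments. The remaining $t$-integral is smooth after the map
$t = T u/(1-u)$, $T = \sqrt{p + 1/r_0^2}$, and 64 Gauss–Legendre nodes are
converged to ~1e-15 over the supported exponent range (checked against
200-node values and the grid oracle).

*Oracle path.* `quadrature_oracle()` integrates arbitrary Gaussian-envelope
integrands on Becke-partitioned atom-centered grids (Gauss–Legendre radial
map $r = s\,x^2/(1-x)^2$, product angular grids), escalating through three
grid levels until successive levels agree below tolerance and failing loudly
otherwise. It shares no code with the analytic path. The randomized
acceptance sweep (200 shell-pair/site cases, exponents 0.1–50, separations
0–10 bohr) observes worst-case deviations below 1e-9 against the 1e-8
criterion.

Derivative integrals are never transcribed separately: every center
derivative uses the angular-momentum identity
$\partial_A \langle i| = 2a\langle i+1| - i\langle i-1|$ against the same
kernels, and operator-center derivatives follow from translational
invariance, $\partial_R = -(\partial_A + \partial_B)$. This guarantees
internal consistency between values and gradients by construction.

## Gradients

The gradient of the embedded RHF energy collects: the standard
core-Hamiltonian, two-electron and Pulay terms (the energy-weighted density
$W = 2\sum_k \epsilon_k c_k c_k^T$ contracting $\partial S$); the
field-integral derivative contraction (an `E` supertensor of A-weighted
density products contracted against $\partial F^{(e)}$ in one integral-direct
pass, no derivative arrays stored); the effective-polarizability chain
$\partial A = A (\partial T) A$ — exact because the atomic $\alpha$ are
geometry-independent, with the Thole $\lambda$ factors differentiated along
with the bare tensor; the RI overlap chain
$\partial S^{-1} = -S^{-1} \partial S\, S^{-1}$; CPP integral derivatives;
and the classical damped-field and Coulomb chains. The two-density exchange
contraction (`jk_gradient_corrections(system, D1, D2)`) keeps separate
density labels as the seam for response-type gradients.

Validation protocol, fixed in the suite: central differences with step
1e-4 bohr, SCF converged to 1e-12, absolute tolerance 1e-6 hartree/bohr, for
nuclear, charge and site displacements; net force (1e-8) and net torque
(1e-7) must vanish for isolated systems.

## SCF engine

Closed-shell RHF with DIIS (subspace 8) and a plain damping fallback;
convergence requires both max$|FDS - SDF| \le$ 1e-8 and $\Delta E \le$ 1e-10
by default (tests tighten to 1e-10/1e-12 before finite differencing).
The orthogonalizer drops overlap eigenvalues below $10^{-8}$ of the largest,
so linearly dependent bases run through the same code path; the RI inverse
switches to the pseudoinverse on the same threshold. The initial guess is the
core Hamiltonian including $H_{pol}$ and the electrostatic embedding. MM
point charges enter the core Hamiltonian undamped (plain electrostatic
embedding), alongside the polarization corrections; Pauli-repulsion core
potentials on MM atoms are out of scope. The MM–MM charge Coulomb energy is
excluded by default (`include_mm_coulomb`), since it is constant for a fixed
environment; gradients are consistent with whichever convention is chosen.

## Synthetic fixtures

`generate_solvent_shell()` emulates the geometry statistics of an
equilibrated apolar solvent shell without molecular dynamics: rigid linear
three-site molecules (site spacing 2.2 bohr), rejection-sampled uniformly in
a shell at a toy-liquid number density (default 1e-3 molecules/bohr$^3$)
with a minimum interatomic separation of 3.5 bohr and a solute exclusion
sphere; small partial charges ($+q$, $-2q$, $+q$ with $q = 0.0327\,e$,
matching the magnitude typical of alkane force-field charges) and
Applequist-style atomic polarizabilities (0.91 and 5.93 bohr$^3$,
hydrogen-like and carbon-like). Fixtures are pure functions of their seed.

What the generator does *not* emulate: thermal disorder consistent with a
force field (no Boltzmann sampling), molecular flexibility, realistic radial
distribution functions, or long-range bulk effects. Tests that pass on these
shells therefore demonstrate the correctness of the embedding machinery, not
the fidelity of any particular solvent model.

One fixture deserves its own note. Replacing a distant molecule's atomic
dipoles by a single isotropic site discards the molecular polarizability
*anisotropy*; for one linear molecule aligned with the probe field this
alone changes the polarization energy by ~20%, and randomly oriented shells
only average it away as $1/\sqrt{N}$. The far-shell check therefore uses a
designed shell — at each shell direction, three identical molecules oriented
along mutually orthogonal axes at equal radius — which cancels the leading
(second-Legendre) orientation term exactly, emulating the orientational
averaging of a bulk shell with a desk-scale molecule count. On that fixture,
coarse-graining at ~9 molecular diameters changes the state polarization
energy by 0.3–0.8%, and the 1% tolerance of the check is a documented
property of this fixture design, not of single-molecule graining.

## Coarse-graining

A molecule whose atoms all lie beyond the cutoff (default 5 Å through the
configuration layer) from every QM atom is replaced by one site: its
molecular polarizability tensor is computed from its own interacting-dipole
system, diagonalized, and the eigenvalue mean taken as the scalar
polarizability — rotation invariant by construction. The site is placed on
the member atom closest to the molecule's geometric center (atomic masses
are not part of the environment schema; for the bundled symmetric fixtures
the geometric center coincides with the center of mass). The grained site
keeps its molecule's charges on its exclusion list.

## Parameter summary

| parameter | default | units | role |
|---|---|---|---|
| `thole_a` | 2.1304 | — | Thole damping strength of $T^{(ij)}$ |
| `field_c` | 1.0 | — | damping radius factor, $r_0 = c\,\alpha^{1/3}$ |
| `ri_mode` | `exact-same-site` | — | same-site treatment of the self-interaction |
| `conv_commutator` | 1e-8 | a.u. | SCF convergence on max$|FDS-SDF|$ |
| `conv_energy` | 1e-10 | hartree | SCF convergence on $\Delta E$ |
| pseudoinverse cutoff | 1e-8 | relative | overlap singular-value drop threshold |
| `coarse_grain_cutoff` | 5 | Å | molecule-to-QM distance for graining |
| shell `density` | 1e-3 | bohr$^{-3}$ | fixture number density |

## Problem sizes

The test and acceptance workloads are deliberately desk-scale: bases of 2–7
contracted AOs (H$_2$, HeH$^+$, minimal-basis H$_2$O), environments of up to
three explicit sites plus two charges for the finite-difference matrix,
24-site generated shells for the end-to-end runs, and 54-site triad shells
for the coarse-graining checks. Finite differencing covers every coordinate
on the small fixtures and one representative particle of each kind (sampled
components) on the largest, which keeps the whole suite within a sensible
interactive budget while still exercising every displacement type.

## Known limitations

* s and p shells only; d functions and effective core potentials are
  rejected with a clear error.
* Restricted closed-shell HF only; the generalized J/K and two-density
  gradient contractions are the designed seam for response and
  multi-state layers, not a substitute for them.
* Dense $N_{pol}^3$ LU inversion of the dipole system and dense ERI storage:
  appropriate at desk scale, no sparsity or iterative solvers.
* Anisotropic atomic polarizabilities, fluctuating charges, Drude
  oscillators, and periodic boundary conditions are out of scope.
* The pseudoinverse gradient path assumes the dropped overlap subspace does
  not change dimension along the displacement (the usual caveat of
  fixed-threshold pseudoinverses).
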