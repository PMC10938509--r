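# polembed

Polarizable QM/MM embedding by the direct reaction field (DRF) method, with
exact (damped) polarization integrals, a minimal restricted Hartree–Fock
engine, and analytical gradients — at desk scale, in R.

## The problem

Electronic-structure calculations on a chromophore in solution must account
for the *instantaneous* electronic polarization of the environment: the
solvent's electrons respond to where the QM electrons are, screening Coulomb
interactions and differentially stabilizing states of different polarity.
Conventional electrostatic embedding (fixed point charges in the core
Hamiltonian) misses this entirely, and mean-field polarizable embeddings make
the Hamiltonian depend on one particular electronic state.

The direct reaction field approach instead puts the environment response into
the Hamiltonian itself. The MM region carries, besides point charges
$Q_n$, isotropic atomic polarizabilities $\alpha_i$ whose induced dipoles
interact through the (Thole-damped) dipole field tensor
$T^{(ij)}$. Eliminating the dipoles exactly gives the effective
polarizability supermatrix

$$A = (\boldsymbol{\alpha}^{-1} - T)^{-1}, \qquad p = A f,$$

and the polarization energy operator

$$\hat{H}_{pol} = -\tfrac12\, \hat{f}^{\,T} A\, \hat{f}, \qquad
  \hat{f} = \sum_a \hat{f}^{(e)}_a + f^{(n)},$$

where $\hat f^{(e)}_a$ is the (damped) electric-field operator of electron
$a$ at the polarizable sites and $f^{(n)}$ collects the damped fields of the
nuclei and MM charges. Because $\hat H_{pol}$ is quadratic in the fields it
splits into

* a **two-electron** correction
  $(\mu\nu|\lambda\sigma)_{pol} = -F^{(e)T}_{\mu\nu} A\, F^{(e)}_{\lambda\sigma}$,
  applied through factorized Coulomb/exchange builds;
* a **one-electron** correction: the nucleus–electron cross term plus the
  electron self-interaction, evaluated with a resolution of the identity over
  the primary basis and — by default — exact same-site core-polarization-
  potential (CPP) integrals;
* a **zero-electron** constant $-\tfrac12 F^{(n)T} A F^{(n)}$ that contains
  the full classical MM polarization energy.

One Hamiltonian therefore serves every electronic state, and the
state-dependent induced dipoles and polarization energies are recovered
afterwards as expectation values. All polarization integrals
($\int \mu\, C(r) \,r_\alpha/r^3\, \nu$ and the CPP kernel
$C^2(r)\,r_\alpha r_\beta / r^6$) are evaluated exactly — no multipole
Taylor expansions — which is what makes smooth analytical gradients with
respect to nuclei, MM charges *and* polarizable sites possible.

The package implements the full stack: the classical Thole/Applequist model
(including coarse-graining of distant molecules to single isotropic sites),
Gaussian s/p-basis integrals with an independent grid-quadrature oracle, the
DRF Hamiltonian corrections, the RHF engine, the gradient contraction
machinery, synthetic solvent-shell fixtures, and a command-line interface.

## Worked example

Hydrogen molecule in a synthetic apolar solvent shell of eight polarizable
three-site molecules:

```r
library(polembed)

h2  <- data.frame(element = c("H", "H"), x = 0, y = 0, z = c(0, 1.4))  # bohr
env <- generate_solvent_shell(seed = 1, n_molecules = 8, qm_exclusion_radius = 5)
env
#> <pol_environment> 24 point charges, 24 polarizable sites
#>   thole_a = 2.1304, field_c = 1, exclusions = 72

fit <- run_rhf(h2, basis = "sto-3g", environment = env)
fit
#> <scf_state> E_total = -1.11695454869 hartree (converged in 4 iterations)
#>   24 polarizable sites; E0_pol = -0.0089348541, state E_pol = -5.767843e-06

glance(fit)
#> # A tibble: 1 x 8
#>   E_total converged n_iter  n_ao n_sites n_charges   E0_pol E_pol_state
#> 1   -1.12 TRUE           4     2      24        24 -0.00893 -0.00000577
```

`E0_pol` is the zero-electron reaction-field constant (dominated by the
response of the shell to the QM nuclei and its own charges), and
`E_pol_state` is the ground-state mean-field polarization energy — the
dipoles induced by the *net* field of the neutral molecule, hence small.
Relative to `run_rhf(h2)` in vacuum the shell binds the solute by
2.4e-4 hartree. Per-site induced dipoles and gradients:

```r
head(tidy(state_polarization(fit)), 3)
#> # A tibble: 3 x 8
#>      id     x     y      z         px         py         pz    p_norm
#> 1     1 -8.69 -5.31 -4.25  0.000289   -0.000426  -0.000390  0.000646
#> 2     2 -8.31 -4.09 -2.45  0.000160   -0.00134   -0.000740  0.00154
#> 3     3 -7.93 -2.88 -0.655 0.00000926 -0.0000702 -0.0000476 0.0000853

total_gradient(fit)
#> <gradient_report> 50 particles; max |g| = 0.0284022 hartree/bohr;
#>   net force = ( 5.29e-20, -4.45e-19,  8.37e-16)
```

The gradient covers all 50 particles (2 nuclei, 24 charges, 24 sites); the
vanishing net force reflects the analytic translational invariance of every
term. `autoplot(fit)` draws the SCF convergence trace and
`autoplot(state_polarization(fit))` the induced-dipole profile.

The same runs are available from a shell:

```sh
Rscript inst/cli/polembed.R energy --config run.yaml --out report.json
Rscript inst/cli/polembed.R gradient --config run.yaml
Rscript inst/cli/polembed.R make-fixture --seed 7 --n-molecules 8 --out env.yaml
```

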