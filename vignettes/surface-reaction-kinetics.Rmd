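---
title: "From harmonic frequencies to surface-reaction rate constants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From harmonic frequencies to surface-reaction rate constants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfkin)
```

## The problem

Quantum-chemical studies of reactions on mineral surfaces — here, the
dimerization of two HCN molecules into iminoacetonitrile (IAN, HN=CH–CN)
on forsterite (Mg₂SiO₄) facets — end with a set of stationary points:
optimized minima and transition states, each carrying electronic energies
at one or two theory levels and a harmonic frequency set from a partial
Hessian. Everything a kineticist wants comes *after* that point, and that
post-processing is what this package implements: zero-point and thermal
corrections, Gibbs energy profiles, unimolecular rate constants from
canonical transition-state theory (TST) and RRKM theory, Eckart tunneling
corrections, half-lives, and Arrhenius analysis. The electronic-structure
step itself is out of scope; a synthetic generator with known ground truth
stands in for it so every stage is testable.

## Thermochemical model

For a surface-anchored species only the vibrational degrees of freedom of
the mobile atoms (adsorbates plus first surface layer) are thermally
active: there are no free translations or rotations, no pressure term, and
electronic degeneracy is 1 (all species are closed shell). The enthalpy at
0 K is the electronic energy plus the zero-point energy,

$$\Delta H(0\,\mathrm{K}) = \Delta E + \Delta\mathrm{ZPE}, \qquad
\mathrm{ZPE} = \tfrac{1}{2} N_A h c \sum_i \tilde\nu_i ,$$

and the Gibbs energy adds the harmonic-oscillator thermal internal energy
and entropy, $\Delta G(T) = \Delta H - T\Delta S$, with the standard HO
closed forms per mode ($x = hc\tilde\nu/k_BT$):

$$U_{\mathrm{vib}} - \mathrm{ZPE} = RT\sum_i \frac{x_i}{e^{x_i}-1}, \qquad
S_{\mathrm{vib}} = R\sum_i\left[\frac{x_i}{e^{x_i}-1} -
\ln\!\left(1-e^{-x_i}\right)\right].$$

Imaginary modes (stored as negative wavenumbers — exactly one for a
transition state, none for a minimum) never enter these sums. Modes below
5 cm⁻¹ are excluded with a warning: they sit at the noise floor of
finite-difference Hessians and would otherwise inject spurious entropy.
Composite energetics follow the "high//low" convention: the electronic
energy is a single point at the high level on the low-level geometry, and
all vibrational corrections always come from the low (geometry) level.
Electronic energies rest in hartree and convert to kJ mol⁻¹ only at
reporting boundaries; the constants are CODATA-2018, whose differences
from any other modern set are far below the 0.1 kJ mol⁻¹ reporting
precision.

## Numerical Hessians

`central_difference_hessian()` mirrors the frequency procedure used for
slab models: each mobile atom is displaced by ±0.003 Å along each
Cartesian axis; diagonal second derivatives use the 3-point central
formula and off-diagonals the 4-point (±,±) formula (the displacement
scheme fixes only the stencil points; the off-diagonal formula is this
package's choice). The matrix is symmetrized as $(H+H^\top)/2$ and
mass-weighted; eigenvalues map to wavenumbers as
$\mathrm{sign}(\lambda)\sqrt{|\lambda|}/2\pi c$. Central differences are
exact on quadratics up to round-off, which the tests exploit as an
analytic oracle. The stationary-point precondition is checked with a
Richardson-extrapolated numerical gradient (tolerance 10⁻⁶ kJ mol⁻¹ Å⁻¹);
plain central differences would report an $O(h^2)$ phantom gradient on
anharmonic potentials such as the Morse test case. No
translational/rotational projection is applied by default — the mobile
subspace of an anchored species is not translation-invariant — but a
projection flag exists for gas-phase test molecules. Second derivatives
are energy-based; no frequency scaling is applied.

## Rate constants

The canonical TST (Eyring) rate is
$k = (k_BT/h)\,e^{-\Delta G^\ddagger/RT}$ with σ = 1 throughout (surface
sites are distinguishable). The microcanonical route is RRKM adapted to
surface reactions, i.e. vibrations only:

$$k(E) = \frac{N^\ddagger(E-E_0)}{h\,\rho(E)}, \qquad
k(T) = \frac{\int k(E)\rho(E)e^{-E/k_BT}\,dE}
            {\int \rho(E)e^{-E/k_BT}\,dE}.$$

Sums and densities of states come from a direct count by sequential
convolution on a grained energy grid (default grain 5 cm⁻¹, ceiling
$E_0 + 40\,k_BT$). Two numerical choices matter here:

* **Per-level binning.** Each harmonic level $n\tilde\nu$ is placed in the
  bin nearest its exact energy, rather than rounding the *frequency* to a
  grain multiple once (the classic Beyer–Swinehart recursion). With
  frequency rounding the energy error of a state grows linearly with its
  quantum number, which is fatal for low surface modes; with per-level
  binning it is bounded by half a grain for every state.
* **Exact energy moments.** Each bin also carries the exact mean energy of
  its states, and the canonical Boltzmann sums use those means instead of
  the grid positions. Graining then contributes only a within-bin
  Jensen-type error of order $(\beta\,\mathrm{grain})^2$.

The payoff is measurable: canonical RRKM and Eyring rates built from the
same harmonic inputs agree to better than 0.05% at 150–300 K on the
synthetic cases (the dual-route oracle the test suite enforces at 1%), and
halving or doubling the grain moves rates by far less than 0.5%. A
truncation diagnostic refuses grids whose top 15% still carries more than
0.1% of the Boltzmann mass.

Tunneling uses the asymmetric Eckart model, parameterized entirely by the
forward and reverse ZPE-corrected barriers and the transition state's
imaginary wavenumber, with the transmission probability in the standard
closed form (cosh ratios evaluated overflow-safely) and

$$\kappa(T) = \frac{e^{V_f/k_BT}}{k_BT}\int_0^\infty P(E)\,e^{-E/k_BT}\,dE$$

by adaptive quadrature. κ is applied as a canonical multiplicative factor
on the classical rate (k_tunn = κ·k_class), not convolved microcanonically.
The default reporting policy applies κ only to steps whose imaginary mode
exceeds 800 cm⁻¹ — proton-transfer-like motion, such as the HCN
deprotonation — because heavy-atom C–C couplings (≈300–500 cm⁻¹) tunnel
negligibly at these temperatures; `tunnel = "all"` or `"none"` overrides.
For steps whose reverse ZPE-corrected barrier is non-positive (TS/product
inversion) the 1-D Eckart model is undefined and κ falls back to 1 with a
warning. Half-lives are $t_{1/2} = \ln 2/(3600\,k)$ hours; rates below
10⁻¹⁹ s⁻¹ are floored to zero only when rendering tables, never in
computation.

## The synthetic generator

`generate_reaction_case()` builds a full reaction path — reactant complex,
one TS and one minimum per step — with `n_modes = 30` real wavenumbers per
node (an adsorbate plus first-layer mobile set at realistic state-count
workloads), sampled uniformly from (75, 3600) cm⁻¹, and one imaginary TS
mode per step (1250 cm⁻¹ for deprotonations, 420 cm⁻¹ for C–C couplings).
Calibration solves the *electronic* energies so the pipeline reproduces
prescribed ΔG‡/ΔG (or ΔH(0 K)) targets: with a single calibration
temperature the solve is linear and exact, keeping the sampled frequencies
— and hence the temperature dependence — untouched and interpretable.

The packaged reference cases must match published Gibbs values at 150,
200 *and* 300 K simultaneously, which over-determines a single energy:
the activation entropy profile must also be shaped. For those specs the
generator (i) gives surface minima a block of ten low "lattice" modes
(65–245 cm⁻¹, emulating first-layer phonons and providing the entropy
budget), and (ii) replaces the k lowest modes of each calibrated node by
two fitted mode values (with multiplicities) plus inert 3700 cm⁻¹ padding,
solving the two residual temperatures exactly after pinning the energy at
200 K. An analytic feasibility screen over k keeps the 2-D solves
well-posed; achieved targets land within 0.04 kJ mol⁻¹ of the published
values. `perturb_case()` adds Gaussian electronic-energy noise (one draw
per non-reference node, applied to both theory levels) to propagate
DFT-level uncertainty — the ~4 kJ mol⁻¹ scale at which the (111)DE
TS/product inversion flag becomes genuinely undecidable.

What the generator does *not* emulate: real anharmonicity, mode coupling,
coverage effects, or the actual DFT frequencies and absolute energies of
the slab models (which are not published). Passing tests therefore
demonstrate the correctness of the post-processing machinery and the
internal consistency of the published table arithmetic — not an ab initio
reproduction of the underlying electronic structure.

## Profile validation and binding energies

`validate_profile()` flags transition states lying below an adjacent
minimum on the ZPE-corrected profile, graded against a DFT-accuracy
tolerance of 4 kJ mol⁻¹ (overridable): the (111)DE case, with its product
1.8 kJ mol⁻¹ *above* the TS, reads "within DFT accuracy" — effectively
barrierless or slightly inverted, not distinguishable at this level.
Endothermic and barrierless steps are flagged alongside. Intrinsic step
barriers are reported both against the preceding minimum and against the
global reference, since both conventions appear in practice. Binding
energies follow BE = E(complex) − E(surface) − ΣE(adsorbates), negative =
bound; the ΔBE vs ΔΔH cross-check is advisory only because adsorption and
reaction energetics typically come from different theory levels.

## Problem sizes and reproducibility

The test suite and the acceptance script run the full pipeline at the
study's own scale: 30-mode species, six reference cases, 20-case oracle
sweeps, grain 5 cm⁻¹, and 200–500-replicate Monte-Carlo sensitivity runs —
a few seconds each on one core. Every random draw flows through an
explicit integer seed (one private RNG stream per generated artifact), so
identical configurations yield byte-identical fixtures and outputs; the
run report records seed, configuration hash, package version, and every
profile flag raised during the run.

## Known limitations

No variational TST, no multidimensional or small-curvature tunneling, no
master-equation pressure dependence, no hindered-rotor or quasi-harmonic
entropy corrections, and no diffusion/encounter (Langmuir–Hinshelwood
site-meeting) kinetics: elementary steps only. The species schema is this
package's own (`schema_version: 1`); adapters for native
electronic-structure outputs would sit in front of `read_species()`.
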