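# surfkin

Harmonic thermochemistry and RRKM/Eckart kinetics for unimolecular
reactions on mineral surfaces, with the dimerization of HCN to
iminoacetonitrile (IAN, HN=CH–CN) on forsterite (Mg₂SiO₄) facets as the
worked system.

A quantum-chemical surface study ends with stationary points: optimized
minima and transition states, each with electronic energies at one or two
theory levels and a harmonic wavenumber set from a partial (mobile-atom)
Hessian. `surfkin` implements everything downstream of that, for
computational surface chemists and astrochemists who need kinetics out of
slab calculations:

- **Thermochemistry** — ZPE, harmonic-oscillator thermal corrections and
  entropies (vibrations only: adsorbed species have no free translations
  or rotations), ΔH(0 K) = ΔE + ΔZPE and ΔG(T) = ΔH − TΔS;
- **Profiles** — composite "high//low" energy assembly (single-point
  energy at the high level on low-level geometries), ZPE-corrected
  reaction profiles, intrinsic per-step barriers, TS/product inversion
  detection against a ~4 kJ mol⁻¹ DFT-accuracy tolerance, and
  binding-energy bookkeeping (BE = E(complex) − E(surface) − ΣE(ads));
- **Kinetics** — canonical TST, k = (k_BT/h)·exp(−ΔG‡/RT); surface-adapted
  RRKM, k(E) = N‡(E−E₀)/(h·ρ(E)), with exact state counts on a grained
  energy grid; asymmetric Eckart tunneling κ(T) parameterized by the
  forward/reverse ZPE-corrected barriers and the TS imaginary wavenumber;
  half-lives t½ = ln2/(3600·k) in hours; Arrhenius tables and fits;
- **Synthetic ground truth** — a generator that builds full reaction paths
  (30 modes per stationary point) whose electronic energies are solved so
  the pipeline reproduces prescribed ΔG‡/ΔG or ΔH(0 K) targets exactly,
  plus model potentials with analytic Hessians for the numerical
  vibrational machinery. No electronic-structure code is needed anywhere.

Published reference values for the six HCN/forsterite cases — Gibbs
barriers, rate constants and half-lives at 150/200/300 K, profile
enthalpies, adsorption energies — ship as plain TSV under
`inst/extdata/reference/` and drive the calibrated fixtures.

## Worked example

The (111)DE case is the interesting pathology: after ZPE corrections the
product ends up *above* its transition state.

```r
library(surfkin)

case <- generate_reaction_case(profile_case_specs()[["(111)DE"]])
prof <- build_profile(case$path, "bhlyp//pbe")
prof
#> <reaction_profile> (111)DE @ bhlyp//pbe
#>          label             role step       dE   dH0
#>      R_(111)DE reactant_complex <NA>   0.0000   0.0
#>  TS_(111)DE_CC transition_state   CC 195.0772 142.8
#>      P_(111)DE  product_complex <NA> 263.6407 144.6
validate_profile(prof, tolerance = 4)
#>               type step      node   gap            severity
#> 1        inversion   CC P_(111)DE   1.8 within_dft_accuracy
#> 2 endothermic_step   CC           144.6
```

The ZPE-corrected barrier is 142.8 kJ/mol and the reaction enthalpy
144.6 kJ/mol: the 1.8 kJ/mol inversion is inside DFT accuracy, so the step
is "barrierless or slightly inverted" — and strongly endothermic either
way. Rates for the fastest C–C coupling channel, (101)BC:

```r
rec <- step_rates(generate_reaction_case(table1_case_specs()[["(101)BC"]])$path,
                  "bhlyp//pbe", "CC", c(150, 200, 300))
rec[, c("temperature", "dG_act", "dG_rxn", "k_tunn", "half_life")]
#>   temperature dG_act dG_rxn   k_tunn half_life
#> 1         150   52.6  -53.9 1.51e-06  1.28e+02
#> 2         200   52.8  -52.5 6.76e-02  2.85e-03
#> 3         300   53.6  -48.8 2.91e+03  6.62e-08
```

A 52.6 kJ/mol barrier at 150 K gives a half-life of ~130 h; at 300 K the
reaction is effectively instantaneous. `write_rate_table()` renders such
records in the customary table layout (energies to 1 decimal, rates to 2
significant figures, k < 10⁻¹⁹ s⁻¹ as 0 with infinite half-life).

## Analysis workflow

The study's analyses are numbered scripts under `analysis/`, each a thin
narrative driver over the package that writes its tables under `results/`:

| script | what it does |
|---|---|
| `01_gas_phase_profile.R` | uncatalyzed baseline (311.3 kJ/mol barrier, +39.1 endothermic) |
| `02_surface_profiles.R` | ZPE-corrected profiles on (120)/(101)/(111), inversion flags |
| `03_binding_energies.R` | ΔBE per site and cross-site differences from adsorption energies |
| `04_rate_table.R` | full 150/200/300 K table: ΔG‡, ΔG, RRKM k, t½ for all six cases |
| `05_arrhenius.R` | 50–300 K Arrhenius plots/fits; Eckart tunneling on the deprotonation |
| `06_sensitivity.R` | 4 kJ/mol Monte-Carlo: inversion-flag stability, rate spread |

Run them from the repository root after installing, e.g.
`Rscript analysis/04_rate_table.R`.

## Species files

Stationary points are YAML (`schema_version: 1`): `label`, `role` (one of
reactant_complex / intermediate / transition_state / product_complex /
bare_surface / free_molecule), `energies` (theory level → hartree),
`wavenumbers` (cm⁻¹; imaginary modes as negative numbers or `"1000i"`),
optional `geometry` and 0-based `mobile_mask`. A transition state must
carry exactly one imaginary mode; minima none. See
`inst/extdata/species/gas_TS.species` for a synthetic example and the
vignette (`vignettes/surface-reaction-kinetics.Rmd`) for the model,
numerical choices, and known limitations.
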