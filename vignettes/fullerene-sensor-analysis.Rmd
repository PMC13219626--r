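---
title: "Post-DFT analysis of fullerene-based drug sensors: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-DFT analysis of fullerene-based drug sensors: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fullersense)
```

## Scope

`fullersense` post-processes quantum-chemistry result summaries for a family
of C60-based nanostructures (pristine C60 and single-atom Al- or Zn-doped
cages) evaluated as chemiresistive sensors or adsorbents for a small-molecule
analyte. The package does **not** run electronic-structure calculations: its
inputs are frontier orbital energies, total energies, excitation line lists,
and electric tensors, carried in a `result_bundle`. From those it computes
conceptual-DFT reactivity descriptors, adsorption/sensing figures of merit,
broadened spectra, and real-space density topology on analytic promolecular
model densities.

A reference data set transcribed from a published computational study of these
systems ships as `paper_fixtures()`; the analysis scripts under `analysis/`
recompute every desk-reproducible number in it.

## Data model

A `result_bundle` collects, per system:

- `orbitals`: an `orbital_spectrum` (energies in eV, occupations in [0, 2]);
  `frontier_orbitals()` picks the HOMO/LUMO pair at the occupation > 0.5
  threshold.
- `energies`: an `energy_record` with the total energy and optional isolated
  per-atom energies, canonicalized to kcal/mol on input (`hartree`, `kJ/mol`,
  and `eV` tags are converted with pinned CODATA factors; see
  `physical_constants()`).
- `geometry` (Angstrom), `electric` (dipole in Debye, polarizability tensor in
  a.u.), `excitations` (energy/wavelength/oscillator strength, with the
  E·λ = hc identity enforced), and optional atomic charges.

Bundles round-trip through a canonical JSON schema (`read_bundle()` /
`write_bundle()`); geometries through XYZ and volumetric data through Gaussian
cube files (z-fastest ordering, bohr axes).

## Reactivity descriptors

From the frontier pair (ε_H, ε_L), `reactivity_descriptors()` returns

- gap: HLG = ε_L − ε_H,
- hardness: η = HLG / 2 and softness S = 1 / (2η),
- chemical potential: µ = (ε_H + ε_L) / 2,
- maximum charge acceptance: ΔNmax = −µ / η.

For a degenerate frontier (η = 0), S and ΔNmax are returned as `NA` rather
than infinities, and the flag propagates through `ect()`. The
electrophilicity-based charge transfer between a free sensor and its complex
is the literal difference `ect = ΔNmax(sensor) − ΔNmax(complex)`; a negative
value is reported as `analyte_to_sensor`. Note that for one doped pair in the
reference table the printed ECT value (−0.26) has the opposite sign from what
this formula gives on the printed descriptor values (+0.27); the fixture
stores the printed value verbatim and the tests do not assert that cell.

## Sensing metrics and the conductivity unit convention

- Adsorption energy: `E_ads = E_complex − (E_sensor + E_drug)` (kcal/mol).
- Cohesive energy: `(E_total − Σ E_atom) / n_atoms`.
- Recovery time (transition-state / Arrhenius form):
  `τ = ν0⁻¹ · exp(−E_ads / (R·T))` with R·T in kcal/mol (0.5922 at 298 K) and
  attempt frequency ν0 = 1e12 s⁻¹ by default. `classify_regime()` labels
  τ ≤ 1 s as `reversible-sensor`, τ ≥ 1e6 s as `adsorbent`, and
  `intermediate` otherwise (thresholds configurable).
- Conductivity: `σ = A · T^{3/2} · exp(−HLG / (2k))` with A = 6e5 and T = 298 K
  by default. Two conventions for `k` are provided because they differ
  enormously and only one matches the reference table:
  - `mode = "physical"`: k = k_B·T in eV (0.02568 eV at 298 K), the
    dimensionally consistent reading of the exponent for a gap in eV;
  - `mode = "paper_compat"`: k = 2.4777, numerically R·T in kJ/mol at 298 K,
    applied to the gap's bare numeric eV value.

  The reference σ column (×10⁹ S/m) is reproduced within 1% by
  `paper_compat` for all six systems and missed by many orders of magnitude
  by `physical`. This unit-convention finding is documented rather than
  hidden: `paper_compat` is the default in `study_config()` so reports match
  the reference table, and the mode is recorded in every output.

## Spectra

DOS and UV-Vis curves are sums of **unit-area** Gaussians (peak height
2√(ln 2/π)/FWHM), so the integral counts orbitals or total oscillator
strength. Defaults: DOS FWHM 0.3 eV on a −15..0 eV grid (step 0.01); UV-Vis
FWHM 0.333 eV on 0.5..6.5 eV (step 0.005). `dos_gap()` reads the gap the way
one reads a plotted DOS — occupied and virtual manifolds broadened
separately, distance between peak centers — and agrees with the frontier gap
whenever levels are separated by more than the broadening width.
`lambda_max()` reports the global maximum in nm (ties broken toward the
longer wavelength); `ev_nm()` is the hc = 1239.84193 eV·nm involution;
`shift_report()` classifies complexation shifts as red/blue.

## Density topology

`promolecular_field()` evaluates an analytic promolecular density
ρ(r) = Σ_atoms Σ_shells c_i · exp(−r/ζ_i) with closed-form gradient and
Hessian (no numerical differentiation). The hydrogen shell is the standard
single-exponential promolecular density; heavier elements use two-exponential
core+valence parameters chosen by the implementer — topology results asserted
in the tests depend only on the functional form, not on the parameter values.

On top of the field:

- `rdg()` and `signed_density()` implement the NCI reduced density gradient
  and sign(λ₂)ρ classification (threshold 0.01 a.u.);
- `kinetic_density()` provides Thomas–Fermi (and +Weizsäcker) kinetic energy
  densities; `elf()` and `lol()` are the Becke–Edgecombe and Schmider–Becke
  localization indicators, both 0.5 at the homogeneous-gas reference (ELF
  clamps negative Pauli kinetic energy with a warning);
- `energy_densities()` uses the Abramov kinetic estimate
  g = τ_TF + |∇ρ|²/(72ρ) + ∇²ρ/6 and the local virial relation
  v = ∇²ρ/4 − 2g, with h = g + v an exact identity;
- `find_bcps()` Newton-searches for (3, −1) saddle points seeded at atom-pair
  midpoints (≤ 4 Å), with step damping, 1e−8 a.u. gradient tolerance and
  1e−3 bohr deduplication.

The printed wavefunction-based G/V/VIR values in the reference table are not
desk-reproducible from a promolecular density; they are shipped as fixtures
and checked only for the exact VIR = G + V bookkeeping. The promolecular BCP
search is validated instead against closed-form symmetric-dimer results.

## Synthetic scenarios

`scenario_spec()` + `make_pair()` generate sensor/complex/drug bundle triples
whose ground truth is known by construction: the frontier pair equals
µ ± gap/2 exactly, `E_complex = E_sensor + E_drug + eads`, and excitation
lines are placed verbatim, so a noiseless scenario must be recovered by the
pipeline to machine precision. Gaussian jitter (`noise_sd`) displaces only
the eight filler orbitals, never the frontier. All randomness flows from one
integer seed through a locally scoped Mersenne–Twister stream that saves and
restores the caller's `.Random.seed`. `scenario_grid()` alternates
physisorption (E_ads ∈ [−15, −5] kcal/mol) and chemisorption
([−60, −30]) so any grid of n ≥ 2 exercises both regimes.

## Worked example

```{r example}
fx <- paper_fixtures()
reactivity_descriptors(fx$systems$`C60@PCE`$orbitals)

m <- sensing_metrics(fx$systems$C60, fx$systems$`C60@PCE`, fx$drug,
                     sigma_mode = "paper_compat")
c(eads = m$e_ads, tau = m$tau, sigma_1e9 = m$sigma_complex / 1e9)
m$regime
```

## Numerical choices and limitations

- All physical constants are pinned (`physical_constants()`), not looked up
  at run time, so results are bit-reproducible across machines.
- Reported reference comparisons inherit the 2-decimal rounding of the
  printed tables; descriptor tests therefore use a 0.015 absolute tolerance.
- The isolated-C60 UV row in the reference table pairs 360 nm with 2.78 eV,
  which is inconsistent with E·λ = hc (hc/2.78 eV = 446 nm); the fixture
  stores the row verbatim and conversion checks exclude it.
- Promolecular densities have nuclear cusps; gradients/Hessians at a nucleus
  use the symmetric-limit convention (zero contribution from that atom).
- ELF/LOL on a promolecular field use approximate (TF or TF+W) kinetic energy
  densities, as no orbital kinetic energy exists for such a field; they are
  indicators, not wavefunction-quality values.
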