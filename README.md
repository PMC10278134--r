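# blufspec

Post-processing toolkit for computational spectroscopy of BLUF ("blue light
using flavin") photoreceptor domains. Studies of these proteins compare a
dark-adapted and a light-induced state through small spectral fingerprints —
a few-tenths-of-a-ppm NMR shift of the flavin H3 proton, a ~20–30 cm⁻¹
red-shift of the C4=O4 carbonyl stretch, a 0.05–0.08 eV red-shift of the two
lowest absorption bands — computed from MD ensembles with QM/MM electronic
structure. `blufspec` implements everything downstream of the MD and QM
engines:

* **Vibronic absorption spectra.** Normal modes from a mass-weighted Hessian;
  per-mode Huang–Rhys factors from the excited-state gradient in the
  vertical-gradient (VG) approximation, S_j = g_j²/(2ħω_j³); spectral density
  J(ω) = π Σ_j S_j ω_j² δ(ω−ω_j); second-order cumulant lineshape
  g(t) = (1/π)∫ dω J(ω)/ω² [coth(ħω/2k_BT)(1−cos ωt) + i(sin ωt − ωt)];
  absorption spectrum by half-range Fourier transform of e^{−g(t)}.
* **Ensemble spectra.** Per-frame bright-state selection (S2′ = largest
  oscillator strength among states ≥ 2), inhomogeneous broadening by
  convolution with the MD distribution of vertical excitation energies, and
  dark/light alignment by one common energy shift and intensity scale.
* **Ensemble statistics.** Percentile-bootstrap 95% confidence intervals for
  frame-averaged observables and for dark-minus-light differences; optional
  block bootstrap for autocorrelated series; descriptive multimodality
  reports.
* **Structure metrics.** Hydrogen-bond occupancy (donor–acceptor ≤ 3.2 Å and
  D–H···A ≥ 135°), interhelical angle from four-Cα window centroids,
  signed β-sheet dihedral, Kabsch-superposed backbone RMSD.
* **Seeded synthetic-data generators** for all of the above, with analytic
  expected answers, plus PDB / multi-frame XYZ / JSON / CSV readers and
  writers and a subcommand CLI (`inst/scripts/blufspec-cli.R`).

## Worked example

```r
library(blufspec)

cfg <- readRunConfig(overrides = list(outputDir = "blufspec-out"))
res <- runPipeline(cfg)
cat(readLines("blufspec-out/summary.txt"), sep = "\n")
```

```
dark-vs-light comparison (synthetic fixture pipeline)
seed: 1
frames: dark 100, light 200 over replicas 1,2,3
alignment shift: -0.3500 eV, scale: 1.0000
first-maximum shift (light - dark): -0.0700 eV
S1   light - dark:  -0.0737  [ -0.0817,  -0.0658] eV
S2'  light - dark:  -0.0573  [ -0.0711,  -0.0426] eV
H3   light - dark:   0.3202  [  0.1193,   0.5130] ppm
C4=O4 light - dark: -26.7335  [-30.0881, -23.1846] cm-1
H-bond occupancy: dark 0.300, light 0.950
interhelical angle: dark 20.00 deg, light 25.00 deg
sheet dihedral: dark 25.00 deg, light 32.00 deg
```

Reading the output: the synthetic dark and light ensembles are generated
with S1 means 3.20 and 3.13 eV, so the bootstrapped mean difference and the
first maxima of the aligned spectra both recover ≈ −0.07 eV; the alignment
shift (−0.35 eV) is the single offset that brings the computed dark spectrum
onto its reference, applied identically to both states so their peak-to-peak
difference is preserved. The H3 and C4=O4 rows are frame-averaged
observables with percentile-bootstrap 95% confidence intervals; the geometry
rows are trajectory metrics whose fixture values are recovered exactly.

Lower-level entry points (`computeModes()`, `vgCouplings()`,
`buildSpectralDensity()`, `lineshapeG()`, `homogeneousSpectrum()`,
`inhomogeneousSpectrum()`, `alignSpectra()`, `bootstrapMeanCI()`,
`hbondOccupancy()`, `interhelicalAngle()`, `sheetDihedral()`,
`backboneRMSD()`) are documented individually; the methods vignette
(`vignettes/blufspec-methods.Rmd`) derives the model, states every default
and its rationale, and spells out what the synthetic generators do and do
not emulate.

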