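---
title: "Vibronic spectra and structural metrics for BLUF photoreceptor ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vibronic spectra and structural metrics for BLUF photoreceptor ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blufspec)
```

## Scope and scientific setting

BLUF ("blue light using flavin") photoreceptor domains signal not by a
chemical change of their flavin chromophore but by a rearrangement of the
hydrogen-bond network around it, driven by keto–enol tautomerization of a
conserved glutamine. The experimental fingerprints of the light-induced state
are small: a few-tenths-of-a-ppm change of the flavin H3 NMR shift, a
20–30 cm$^{-1}$ red-shift of the C4=O4 carbonyl stretch, and a
0.05–0.08 eV red-shift of the two lowest absorption bands.

`blufspec` implements the *post-electronic-structure* stage of such a study:
everything that happens after an MD engine has produced trajectories and a QM
code has produced Hessians, excited-state gradients, vertical excitation
energies and oscillator strengths per frame. The package does not run MD or
quantum chemistry; it consumes their outputs (or seeded synthetic stand-ins)
and computes

1. vibronic absorption lineshapes in the vertical-gradient (VG) +
   second-order-cumulant model,
2. inhomogeneous broadening over MD ensembles and the dark/light spectral
   comparison with a common shift-and-scale alignment,
3. bootstrapped ensemble statistics for scalar observables, and
4. trajectory structure metrics: hydrogen-bond occupancy, interhelical angle,
   $\beta$-sheet dihedral, backbone RMSD.

## The vibronic model

### Vertical-gradient couplings

Ground-state normal modes $\{\omega_j, \mathbf{q}_j\}$ come from
mass-weighting a Cartesian Hessian (hartree/bohr$^2$), projecting out rigid
translations/rotations and diagonalizing (`computeModes()`); eigenvalues
convert to wavenumbers with
$\tilde\nu = \sqrt{\lambda}\,\times 5140.4845\ \mathrm{cm^{-1}}$ (constants
are centralised in `physConst`, CODATA 2018, 10 significant digits, so tests
are bit-stable).

In the VG approximation the excited-state surface is the ground-state
harmonic surface displaced along each mode; the displacement is read off the
excited-state gradient $\mathbf{g}$ at the ground-state minimum. Projecting
the mass-weighted gradient onto mode $j$ gives the Huang–Rhys factor

$$S_j = \frac{g_j^2}{2\hbar\omega_j^3}, \qquad
  \lambda_j = S_j\,\hbar\omega_j, \qquad \lambda = \sum_j \lambda_j,$$

implemented in `vgCouplings()`. Modes below a low-frequency cutoff
(default 10 cm$^{-1}$) are excluded because $S_j$ diverges as
$\omega \to 0$; the cutoff is shared with `computeModes()` and the excluded
count is reported.

### Spectral density, lineshape, spectrum

The couplings define the spectral density
$J(\omega) = \pi \sum_j S_j \omega_j^2\, \delta(\omega - \omega_j)$,
broadened on a grid with a unit-area Lorentzian or Gaussian kernel
(`buildSpectralDensity()`). The sum rule
$\frac{1}{\pi}\int J(\omega)/\omega\, d\omega = \sum_j S_j\omega_j$
ties the broadened and stick representations to the same reorganization
energy and is enforced to $10^{-4}$ relative in the tests.

The second-order cumulant lineshape is

$$g(t) = \frac{1}{\pi}\int_0^\infty \frac{J(\omega)}{\omega^2}
 \left[\coth\!\Big(\frac{\hbar\omega}{2k_BT}\Big)(1-\cos\omega t)
 + i(\sin\omega t - \omega t)\right] d\omega ,$$

which for stick densities reduces to an exact sum over modes — the default
evaluation route in `lineshapeG()`; trapezoidal quadrature of the broadened
$J$ is available for densities that only exist on a grid. $T = 0$ is handled
as the $\coth \to 1$ limit.

The homogeneous spectrum is the half-range Fourier transform
$\sigma(E) \propto \mathrm{Re}\int_0^\infty e^{i(E-E_\mathrm{vert})t/\hbar
- g(t) - \gamma t/\hbar}\, dt$, evaluated by FFT over the time grid and
interpolated onto the requested energy grid (`homogeneousSpectrum()`). One
self-consistent convention had to be fixed, since variants differ in where
the band sits and what intensity prefactor is applied:

* the **first spectral moment equals $E_\mathrm{vert}$** (a consequence of
  $g'(0) = 0$ in this cumulant form), and the 0–0 line sits at
  $E_\mathrm{vert} - \lambda$;
* the plain lineshape is computed with **no frequency prefactor**
  ($\omega$ or $\omega^3$): the dark/light comparison works on spectra that
  are anyway rescaled to a reference band, so a common prefactor cancels.

Numerical choices: the default time grid has $2^{15}$ points with the extent
chosen so the damped integrand has decayed below $10^{-8}$; the default
Lorentzian damping is $\gamma$ = 1 meV and the default temperature 300 K
(room-temperature spectroscopy). A truncation guard raises an error when the
requested energy window captures less than 99.9% of the spectral area,
measured on the native FFT axis so that grid resolution cannot masquerade as
lost area. These defaults are this package's own choices; the tests pin the
model to analytic results (Franck–Condon Poisson progressions at $T=0$,
Lorentzian limit at $g=0$, Gaussian limit with variance $2\lambda k_BT$ at
high $T$) rather than to any particular parameter set.

### Bright states and inhomogeneous broadening

Along an MD ensemble, the oscillator strength of the second bright band
hops between adiabatic states (typically S3 or S4) from frame to frame.
`selectBrightStates()` therefore defines, per frame, S1 as the lowest state
and S2′ as the state with the **largest oscillator strength among states of
index ≥ 2**; ties resolve to the lower-energy state with a warning.

`inhomogeneousSpectrum()` convolves the homogeneous lineshape with the
empirical distribution of vertical excitation energies: each frame
contributes the homogeneous spectrum re-centred at its own excitation
energy. Frames carry **equal weight by default** — the broadening emulates
the distribution of energies, not of intensities — with an optional
oscillator-strength weighting (`weights =`) for ensembles where intensity
fluctuations matter. S1 and S2′ bands are broadened separately and summed
into one spectrum per protein state before alignment.

`alignSpectra()` mirrors the standard presentation of computed vs measured
spectra: one energy shift and one intensity scale are determined on a
designated spectrum against a reference and applied uniformly to all
spectra, so dark-minus-light peak differences are invariant under the
transform. "First maximum" is operationalized as the lowest-energy local
maximum exceeding 5% of the global maximum on a 1 meV grid.

## Ensemble statistics

`bootstrapMeanCI()` implements the percentile bootstrap (default
`nBoot = 2000`, seed-deterministic resampling) for per-frame observables;
`differenceCI()` bootstraps the difference of two means by independent
resampling of each series, using content-derived RNG substreams so that
swapping the arguments negates the interval exactly. Percentile rather than
BCa was chosen as the simplest defensible flavour for ensemble means of
hundreds of frames.

Treating frames as i.i.d. understates uncertainty for autocorrelated MD
series; a moving-block bootstrap (`blockLen =`) is provided for that case,
and the vignette's advice is to use it whenever the series autocorrelation
time is not clearly below the frame spacing. `multimodalityReport()` gives a
purely descriptive kernel-density mode count — useful because slowly
exchanging protein conformations show up as multimodal chemical-shift
distributions. Note that a KDE bandwidth equal to half the component
separation sits exactly on the two-Gaussian merge threshold; resolving known
structure requires a clearly smaller bandwidth.

## Structure metrics

All metrics consume a `TrajectoryView` (coordinates plus PDB-style
atom/residue annotation) and plain-text selectors (`"21@OH"`).

* **H-bond occupancy** — a frame is bonded when the donor–acceptor distance
  is ≤ 3.2 Å and the hydrogen-bond angle is ≥ 135°. These cutoff values are
  conventionally paired with the angle measured at the **hydrogen**
  (D–H···A), which is the default; because published phrasings of the angle
  criterion are sometimes ambiguous about the vertex atom, it is
  configurable (`vertex =`).
* **Interhelical angle** — per helix, the axis vector runs from the centroid
  of four consecutive C$\alpha$ atoms at the helix start to the centroid of
  four at its end; the angle between the two axis vectors is reported
  unsigned in $[0°, 180°]$, with the axis direction fixed only by N→C
  residue order. The centroid difference is the simplest rotationally
  covariant reduction of the two four-atom windows.
* **$\beta$-sheet dihedral** — the standard signed torsion (right-hand
  convention, $(-180°, 180°]$) over four ordered C$\alpha$ atoms, verified
  against an independent triple-product formula.
* **Backbone RMSD** — least-squares (Kabsch, SVD-based) superposition onto a
  reference frame over backbone atoms; "flexible parts" are excluded via a
  configurable residue-range list, since which spans count as flexible is a
  per-study decision.

## Synthetic-data generators

The `fixtureConfig()` generators are first-class, tested code that emulates
the statistical structure of the study inputs — not their chemistry:

* `genEnergyEnsemble()` draws per-frame, per-state excitation energies from
  Gaussians: 100 dark frames and 200 light frames over three replicas, dark
  S1/S2′ means 3.20/3.95 eV, light 3.13/3.90 eV. The per-state spreads
  (0.029–0.072 eV) are chosen so that ensemble means carry 95% CIs of
  0.004–0.01 eV at these sample sizes; oscillator strengths concentrate on
  one upper state per frame, alternating between the two highest states.
* Scalar observable series use means of 11.6/11.9 ppm (H3 shift) and
  1753/1727 cm$^{-1}$ (carbonyl stretch) with spreads matched to the same
  CI logic.
* `genHBondTrajectory()` places a donor–hydrogen–acceptor triad strictly
  inside (2.8 Å) or outside (3.6 Å) the distance cutoff — at least 0.4 Å
  clear of 3.2 Å — so occupancy equals the configured fraction exactly and
  is robust to cutoff perturbations and floating-point noise.
* `genHelixPair()` builds canonical $\alpha$-helix traces (rise 1.5
  Å/residue, 100° twist, radius 2.3 Å). With the default 22 residues the
  terminal four-C$\alpha$ windows are 18 residues apart — an exact multiple
  of the 3.6-residue helical repeat — so the window-centroid axis coincides
  with the true helix axis and constructed angles are recovered essentially
  exactly; with windows at non-multiple separations the discretization
  error stays below 2°.
* `genToyHessian()` assembles spring-network Hessians that are symmetric and
  translation-invariant by construction, with analytic frequencies for
  diatomics and linear chains.

What these generators deliberately do **not** emulate: anharmonicity,
Duschinsky rotation or Herzberg–Teller intensity borrowing in the vibronic
model; autocorrelation, non-Gaussian tails and slow conformational exchange
in the ensembles; real protein geometry beyond what the metric definitions
need. Passing tests therefore demonstrate that the machinery is correct and
calibrated on data with known structure, not that any particular force
field or QM level reproduces experiment.

## A worked run

```{r pipeline}
cfg <- readRunConfig(overrides = list(outputDir = tempfile("blufspec")))
res <- runPipeline(cfg)
cat(readLines(file.path(cfg$outputDir, "summary.txt")), sep = "\n")
```

The configured dark-minus-light S1 offset (−0.07 eV) is recovered both by
the bootstrapped mean difference and by the first maxima of the aligned
spectra; the H-bond occupancies equal their constructed fractions exactly.
Problem sizes (100/200 frames, $2^{15}$ time points, 1 meV energy grids,
2000 bootstrap resamples) were chosen as realistic for a study of this kind
while keeping a full run around a second.

## Known limitations

* The VG/cumulant model excludes Duschinsky mixing, Herzberg–Teller terms,
  emission and any non-Condon effect; it is a displaced-harmonic-oscillator
  model by design.
* First-maximum detection on empirically broadened spectra is a stochastic
  estimator: with two *independently* sampled 2000-frame ensembles, peak
  positions fluctuate by a few meV even for smooth spectra; sub-meV recovery
  statements hold for ensembles of identical shape (common draws), which is
  how the recovery checks are constructed.
* The i.i.d. bootstrap understates uncertainty on correlated frames — stated
  prominently because it is the default.
* `readPDB()` handles plain single-model coordinate files (no insertion
  codes, no altloc logic); binary MD formats and QM-log parsing are out of
  scope, with the JSON/CSV fixture formats as the documented interchange.
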