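---
title: "Analysing lipid-raft model membranes: monolayer thermodynamics, AC voltammetry and impedance fitting"
author: "raftfilm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing lipid-raft model membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raftfilm)
```

# The system and the measurements

Lipid rafts are liquid-ordered microdomains of cholesterol (Chol) and
sphingomyelin (SM) embedded in a more fluid phospholipid matrix. A standard
laboratory model is a ternary film of DOPC, Chol and SM spread at the
air–water interface, characterised in three stages:

1. **Langmuir monolayers.** Compressing the film while recording surface
   pressure π (mN/m) against area per molecule A (Å²/molecule) yields the
   π–A isotherm. Its derivative gives the reciprocal compression modulus
   \[ C_s^{-1} = -A \left(\frac{d\pi}{dA}\right)_T, \]
   whose maximum classifies the film (gas, liquid-expanded, liquid-condensed,
   solid); extrapolating the steepest branch to π = 0 gives the limiting
   area A₀; local minima of \(C_s^{-1}(\pi)\) mark structural transitions —
   a minimum that stays above a threshold is a *kink* (reorganisation), one
   that drops towards zero is a (partial) *collapse*. π–t traces at fixed
   barrier position measure film stability.
2. **Mixing thermodynamics.** Comparing the mixture with the mole-fraction-
   weighted ideal reference \(A^{id}(\pi) = \sum_i X_i A_i(\pi)\) gives the
   excess area \(A^{Exc} = A_{mix} - A^{id}\), the excess Gibbs energy
   \(\Delta G^{Exc} = N_A \int_0^{\pi} A^{Exc}\,d\pi\), and the percent
   condensation \(\%A = 100\,(A^{id} - A_{mix})/A^{id}\).
3. **Electrochemistry of transferred bilayers.** Films transferred onto a
   gold electrode are probed by AC voltammetry — the series-RC inversion
   \(C = (i_{in}^2 + i_{out}^2)/(\omega E\, i_{out})\) converts the AC
   current components into differential capacitance, which integrates to the
   free charge density and its zero crossing, the potential of zero free
   charge — and by impedance spectroscopy, fitted to the equivalent circuit
   \(R_{sol} + [\,Z_{Q_m} \parallel (R_m + Z_{Q_{sp}})\,]\) with
   constant-phase elements \(Z_{CPE} = 1/(Q (j\omega)^{\alpha})\) for the
   membrane and the hydrated water spacer beneath it.

The package implements each stage as composable functions plus a seeded
synthetic-data generator (`gen_isotherm()`, `gen_stability()`, `gen_acv()`,
`gen_spectrum()`, and the calibrated registry `raft_fixtures()`) so the
entire pipeline is verifiable end to end without laboratory data.

# Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `grid_step` | `preprocess_isotherm` | 0.1 Å² | uniform area grid for a stable smoothed derivative |
| smoothing window | `compression_modulus` | 5 points, degree 2 | Savitzky–Golay quadratic: unbiased derivative for locally parabolic data, noise-suppressing |
| `collapse_threshold` | `detect_transitions` | 10 mN/m | separates collapse (≈ 0 elasticity) from kink; qualitative "reaching zero" made operational |
| `min_depth`, `min_prominence` | `detect_transitions` | 2 mN/m, 0.25 | ignore grid-level ripples and low-pressure wiggles |
| `frac` | `extract_a0` | 0.8 | points within 80% of the local \(C_s^{-1}\) maximum form the "steepest part" |
| `plateau_tol` | `stability_metrics` | 0.5 mN/m per hour | rolling-slope criterion for a stable film |
| `grid` | `excess_gibbs` | 0.5 mN/m | trapezoid step; refining 10× moves results < 0.5% |
| `c_bare`, `c_ideal` | `min_capacitance`/`coverage` | 35, 0.8 µF/cm² | film-free electrode and defect-free bilayer capacitances in the two-capacitor coverage model |
| `weighting` | `cnls_fit` | modulus | each spectrum point contributes its relative error; standard for data spanning decades |
| `topology` | `circuit_impedance` | `default` | spacer CPE in series with the membrane resistance, both shunted by the membrane CPE; an alternative nested topology is selectable |

Units are fixed throughout: Å²/molecule, mN/m, seconds, volts vs Ag|AgCl,
µF/cm², µC/cm², Ω·cm² (with R_m in kΩ·cm² and Q in µF·cm⁻²·s^(α−1), the
conventions used in published parameter tables for supported bilayers).
The excess-Gibbs unit chain (Å² → 10⁻²⁰ m², mN/m → 10⁻³ N/m, times N_A)
is pinned by an exact oracle: a constant 1 Å² excess integrated to
30 mN/m is 6.022 × 30 ≈ 180.7 J/mol.

# The synthetic-data generator

`gen_isotherm()` works in elasticity space. A spec describes a smooth
\(C_s^{-1}(\pi)\) profile — a gas-region baseline joined by a knee to an
expanded-region level `c_le`, a generalised-Gaussian condensed rise to
`cs_max` at `p_peak`, and multiplicative troughs for kinks, collapses and
(optionally) a mid-pressure shoulder — and the isotherm follows by
integrating \(dA/d\pi = -A/C_s^{-1}\). Calibration then uses the package's
own analysis as the measuring stick: the curve is rescaled so
`extract_a0()` reproduces the requested A₀ exactly; the gas baseline is
tuned to the requested lift-off area; the collapse-trough depth is tuned so
the post-collapse branch extrapolates to the requested post-collapse A₀.

`raft_fixtures()` builds the four DOPC:Chol:SM compositions (2:1:1, 1:2:1,
1:1:2, 1:1:1) plus DOPC, Chol and SM singles, calibrated to published
descriptors of this model system: limiting areas (62.0, 48.1, 52.7 Å²; SM
single 50.7 Å²), compression-modulus maxima (98, 169, 162, 125 mN/m), the
equimolar kink at 30 mN/m and partial collapse at 47.8 mN/m, post-collapse
limiting areas (31.0 and 50.5 Å²), percent condensation at 30 mN/m (11.9,
3.9, 3.6%, negative for the equimolar film — obtained by inverting the %A
definition against the single-component fixtures), stability plateaus at 28
and 26 mN/m with a continuously decaying DOPC-rich film, capacitance minima
between 2.6 and 3.5 µF/cm² near −0.2 V with zero-free-charge potentials of
270–330 mV, and impedance spectra generated from the tabulated five-element
circuit parameters of each composition (solution resistance 50 Ω·cm², a
typical value for dilute phosphate buffer, since the tables report only the
membrane elements).

Choices made where no value is published, fixed once: the equimolar A₀
(55.0 Å², between the cholesterol-rich 48.1 and the DOPC-rich 62.0 and above
its post-collapse 50.5); single-component curves with a0 = 90 (DOPC) and
40.5 (Chol) at the high end of literature-typical ranges, which is what
makes the 2:1:1 condensation of 11.9% jointly attainable with its A₀ and
compression-modulus maximum; lift-off areas (105, 42.5, 60 Å²); the 1:1:2
collapse at exactly 45 mN/m where only "approximately 45" is reported. One
reported value carries a unit misprint — the equimolar post-collapse
limiting area appears as "50.5 mN/m" where an area is clearly meant — and is
treated as 50.5 Å².

## What the fixtures do and do not emulate

The descriptor set is jointly over-determined, and three properties of real
data are deliberately *not* reproduced:

* The cholesterol-rich (1:2:1) family cannot connect its condensation at
  30 mN/m, its limiting area and its compression-modulus maximum with a
  monotone elasticity rise; the fixture carries a mid-pressure
  compressibility shoulder (~36 mN/m) that the transition detector reports
  as an extra kink besides the documented one near 50 mN/m.
* Low-pressure mixing behaviour is uncalibrated: excess areas and
  excess Gibbs energies below ~30 mN/m follow from the chosen equation-of-
  state family, so \(\Delta G^{Exc}\) magnitudes and their ordering across
  compositions are indicative only (signs at 30 mN/m: DOPC-rich and SM-rich
  negative, cholesterol-rich near zero, equimolar positive). In particular
  the equimolar film's positive-excess-area window between its kink and its
  collapse is not reproducible jointly with its other descriptors: an
  ideal-mixing reference built on a stiff sterol decays more slowly than
  any mixture curve capped at the equimolar film's own elasticity maximum.
* Passing round-trip tests therefore demonstrates the correctness of the
  analysis chain, not that real troughs produce curves of this family;
  real data carry correlated sensor drift and impurity effects that the
  i.i.d. Gaussian noise options do not model.

# Numerical choices

* Differentiation: Savitzky–Golay (window 5, degree 2) on the uniform area
  grid; one-sided polynomial fits at the ends; a local-quadratic fallback
  for non-uniform grids.
* Transition refinement: parabolic interpolation through the three points
  around each \(C_s^{-1}\) minimum; minima closer than 1.5 mN/m merge into
  one trough (deepest kept).
* Degenerate inputs: duplicate area readings are averaged; sensor pressures
  in (−0.5, 0) mN/m clip to zero, anything lower is rejected; a flat
  capacitance window returns its first grid point flagged degenerate;
  multiple charge-density zero crossings return the most positive with the
  full list attached.
* Charge integration requires an explicit anchor (default: the most
  negative sweep potential with σ = 0); the reported zero-free-charge
  potential depends on that anchor, so synthetic curves carry the anchor
  used in their construction and the CSV dialect round-trips it.
* CNLS: magnitudes are optimised on the log scale (positivity by
  construction), CPE exponents box-constrained to (0, 1], residuals are
  weighted 1/|Z| per point, and the Jacobian is analytic — finite
  differences lose the spacer branch, which contributes under 1% of |Z| on
  a 0.1–1000 Hz grid. A plain joint Levenberg–Marquardt run from a
  perturbed start can still fall into a "vanishing spacer" local minimum,
  so the fit precedes the joint optimisation with two conditioning stages
  (solution resistance and membrane CPE on f ≥ 10 Hz, then membrane
  resistance and spacer CPE on f < 10 Hz) and keeps the better optimum.
  Noise-free spectra from all four tabulated parameter rows are then
  recovered to machine precision from ×2-perturbed starts.
* Standard errors come from the Gauss–Newton curvature at the optimum,
  transformed to the natural scale by the delta method; a singular
  curvature reports them absent. Note the distinction between these fit
  standard errors and replicate spread across repeated experiments —
  published tables typically report the latter.

# Known limitations

* With 1% proportional noise on a 0.1–1000 Hz grid, the membrane resistance
  and spacer CPE magnitude are weakly identified (the spacer contributes
  < 1% of |Z| everywhere); their maximum-likelihood estimates scatter by
  tens of percent and are median-biased even though the optimiser reaches
  the global optimum of every noisy realisation. This matches the large
  uncertainties published for spacer parameters. Precision claims about
  these two parameters should come from replicate spread, longer
  low-frequency tails, or both.
* Phase assignment uses fixed literature bins on the compression-modulus
  maximum; films near a bin edge (e.g. 98 mN/m, labelled LE) are border
  cases and the package reports the underlying number alongside the label.
* The equivalent-circuit topology is assumed, not selected; the alternative
  nested topology is available but no model comparison is performed.

# Problem sizes

Synthetic isotherms use an 800-point area grid (0.02 mN/m pressure grid
internally), ACV sweeps 2 mV steps over −0.8…+0.5 V, impedance spectra 10
points per decade over 0.1–1000 Hz, and stability traces 5 s sampling over
4 h; the Monte-Carlo noise study uses 20 seeds. These sizes resolve every
feature the analyses extract while keeping a full fixture rebuild under a
few seconds.
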