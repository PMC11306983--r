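---
title: "Extracting protein permittivity from THz solution spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting protein permittivity from THz solution spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thzprotein)
```

## The problem

In the terahertz range (here 10–70 cm⁻¹, roughly 0.3–2 THz) the dielectric
response of a protein solution mixes three contributions: bulk water,
the dynamic hydration shells — water within roughly 1.5–2 nm of the protein
surface whose intermolecular dynamics is measurably altered — and the
protein molecules themselves. A THz-TDS measurement delivers one effective
spectrum per sample. `thzprotein` inverts an effective-medium description
of two solutions of the same protein at different concentrations, plus the
pure solvent, to recover the protein's own complex permittivity
ε\*\_p(ν) = ε′\_p + iε″\_p with the aqueous contributions removed.

We use the `e^{-iωt}` time convention throughout, so every passive phase
has ε″ ≥ 0; optical constants relate to permittivity by
ε′ = n² − (α/4πν)² and ε″ = nα/2πν with both ν and the Napierian α in
cm⁻¹.

## The mixing model and its assumptions

The symmetric Bruggeman rule balances the volume-fraction-weighted
polarizabilities of spherical inclusions in a self-consistent effective
medium. Its use here assumes: inclusions small compared with the
wavelength (protein globules of ~5.3 nm versus sub-millimetre waves),
weak absorption by individual inclusions, and no free shape parameters —
which is why Bruggeman is preferred over mixing rules that need
depolarization factors. Maxwell Garnett and other rules are deliberately
out of scope.

Two structural observations anchor the model:

* At 334 mg/mL the protein volume fraction is f_p = c/(1000ρ) ≈ 0.237 and
  the hydration shells — roughly 3–4 protein volumes each
  (`hydration_volume_ratio(5.3, 1.5)` ≈ 2.8 to
  `hydration_volume_ratio(5.3, 2)` ≈ 4.4) — fill essentially all remaining
  volume, so the concentrated solution is a **two-phase**
  (protein + shell) composite.
* At 50 mg/mL the same shells occupy
  f_sh = (1 − f_p)·c_dilute/c_conc ≈ 0.114, the protein f ≈ 0.0355, and
  the rest is bulk water identical to the pure solvent: a **three-phase**
  composite.

The shell-scaling rule assumes non-overlapping shells at the dilute
concentration; `phase_fractions()` warns once f + f_sh exceeds 0.5. Shell
heterogeneity (a radial profile of perturbation) is collapsed into one
effective shell phase.

Solving the two-phase rule for the shell gives
ε_sh = [(1 − 3f_p)ε_p ε_cs + 2ε_cs²]/[ε_p + (2 − 3f_p)ε_cs]; substituting
this into the three-phase rule yields one complex equation per frequency
whose only unknown is ε_p. Its three addends are tracked separately
throughout the package as T1 (protein, weight f), T2 (shell, weight f_sh)
and T3 (bulk water).

## Two solvers and why the reduced one is the default

Clearing denominators shows the combined equation is **quadratic** in
ε_p. The full solver computes both roots at every frequency and keeps a
physical one (loss above −`tol_neg`), preferring the root nearest a hint
(by default the reduced solution, then the previous frequency's choice).
On noiseless forward-mixed data it reproduces the ground truth to ~1e−13
relative error.

But the full equation is badly conditioned: the derivative of the residual
with respect to ε_p nearly cancels between T1 and T2, so realistic scatter
in the measured spectra (about 0.01 on permittivity values) moves the root
by order unity — the extracted modulus can change several-fold or more.
Stable answers from the full solver would require inputs accurate to
better than about 0.001, which THz-TDS does not deliver.

Neglecting T1 (its coefficient f ≈ 0.0355 is the smallest) lowers the
degree: the T2/T3 balance determines ε_sh in closed form,
ε_sh = ε_s(1 + 2C)/(1 − C) with
C = −(1 − f − f_sh)(ε_w − ε_s)/[(ε_w + 2ε_s) f_sh], and inverting the
shell expression gives ε_p uniquely — no branch choice at all. This
**reduced solver** is the default. Its price is a bias of order the
neglected term; the bias shrinks proportionally as f → 0 (verified as a
property test by regenerating scenes with scaled f).

Whether neglecting T1 was legitimate is checked *a posteriori*, per
frequency: both |T2| and |T3| must exceed |T1| by the validity ratio `r`
(default 10, operationalizing "about an order of magnitude";
configurable). Frequencies failing the check, or outside the configured
analysis window (default 10–70 cm⁻¹, where the check holds for
protein-solution spectra), are flagged invalid but retained — never
dropped, never interpolated over.

`sensitivity_scan()` quantifies the contrast directly: it perturbs ε′ and
ε″ of all three inputs with iid zero-mean Gaussians of SD `delta`
(iid Gaussian is the minimal assumption for unstructured scatter;
seed-controlled), re-extracts with both solvers on the *same* draws, and
reports per-frequency relative SD and max/min modulus ratio.

## Numerical choices

* **Quadratic roots** use the cancellation-free form
  q = −(b + sgn·√(b² − 4ac))/2, roots q/a and c/q.
* **Forward mixing** (needed by the generator): the two-phase rule is
  solved by quadratic formula, the three-phase rule by `polyroot()` on the
  cleared cubic followed by Newton polishing; the physical branch is the
  root with ε″ ≥ 0 and Re > 0 nearest the volume-weighted linear mixture.
  For real lossless inputs the result respects the Wiener bounds.
* **Homogeneous degeneracy.** With a consistent fraction triple,
  f(1 − f_p) = f_p·f_sh identically, so when solvent, dilute and
  concentrated spectra coincide the combined equation is satisfied by
  *every* candidate ε_p — the protein is unidentifiable from identical
  spectra. The full solver detects the rank-zero coefficients (relative to
  the input scale) and returns the reduced solution, flagging the
  frequency `degenerate`.
* **Singularities** (vanishing denominators, C = 1) invalidate only the
  frequency concerned; neighbours are solved normally.
* **Negative extracted loss.** Noise can push ε″\_p slightly below zero.
  Values in (−`tol_neg`, 0) with `tol_neg` = 0.05 are reported as-is and
  flagged; more negative values invalidate the frequency. Nothing is
  clamped — clamping would bias spectra toward passivity.
* **Grid alignment** interpolates linearly onto the points of the first
  spectrum inside the common wavenumber interval; extrapolation is never
  performed.
* No smoothing or replicate averaging is applied before inversion by
  default; averaging is left to the caller (the CLI exposes the raw
  per-frequency pipeline only).

## The synthetic generator

`make_scene()` emulates the study conditions end-to-end: bulk water as a
double-Debye relaxation (slow cooperative band Δε ≈ 73, τ ≈ 8.3 ps; fast
band Δε ≈ 2, τ ≈ 0.3 ps; ε_∞ = 2.5 — literature-typical 25 °C magnitudes,
shipped as configurable defaults and **not** fitted to any particular
measurement; tests depend only on the model structure, not these numbers),
hydration shells as retarded, slightly weakened water
(τ × 1.5, Δε × 0.9 by default), and forward Bruggeman mixing at the
experimental fractions (0.237 / 0.0355 / 0.114) on a 10–70 cm⁻¹ grid with
2 cm⁻¹ steps. Measurement noise (SD 0.01 by default, the realistic spread
of THz-TDS permittivity values) is added to the three observable spectra
only; ground truths are stored clean, and identical seeds reproduce scenes
bit-identically.

The **default protein truth** is water-like but retarded and weakened
(Δε = 60 at 9.5 ps plus 1.6 at 0.25 ps over ε_∞ = 2.5). This choice is
deliberate. A dissolved protein exhibits pronounced low-frequency
dispersion with losses close to those of its aqueous environment — its
intramolecular dynamics follows the water's intermolecular relaxation; a
nearly flat ε ≈ 2.5 spectrum is what *dry* protein looks like. The choice
also matters mathematically: with a water-like protein the neglected term
T1 is genuinely small, the order-of-magnitude check passes across the
window, and the quadratic's two roots are well separated with the reduced
solution close to the true branch. With a flat, low-permittivity protein
truth the scene leaves the method's domain of validity altogether: the
reduced solution is biased by order one, and the combined equation
genuinely has **two** fully physical solutions (both implying passive
shells), so no selection rule — physicality, hint proximity, or
continuity in frequency or in f — can distinguish them. The inverse
problem is then two-valued, which is a property of the method, not of the
implementation. The generator therefore defaults to the regime the method
was designed for.

What passing roundtrip tests shows — and what it does not: the generator
produces smooth relaxational spectra with homoscedastic Gaussian noise.
Real THz-TDS data add correlated baseline errors, etalon residues,
thickness uncertainty and frequency-dependent noise, none of which are
emulated; a clean roundtrip therefore validates the algebra and branch
logic, not instrument-grade robustness. Temperature dependence and ionic
conductivity of the solvent are likewise not modelled.

## Problem sizes

The shipped tests and the acceptance script use 31-point grids
(10–70 cm⁻¹, step 2), 100 perturbation draws for sensitivity scans, and
tens of randomized property cases per invariant — sizes at which every
quantity of interest (roundtrip error, spread statistics, validity flags)
is already stable, while the whole suite runs in seconds.

## Known limitations

* The extraction is only as good as the effective-medium description:
  non-spherical aggregates, shell overlap at high concentration, or
  protein–protein correlations violate its assumptions silently.
* The reduced solver's bias is first-order in f; at f ≈ 0.0355 it can
  reach ~20 % of |ε_p| in synthetic scenes. The term-magnitude flag bounds
  the neglected term, not the bias itself.
* No Kramers–Kronig consistency is enforced on extracted spectra; each
  frequency is solved independently.
* Etalon correction, pulse processing and thickness metrology are upstream
  of this package: inputs are assumed to be calibrated n/α or ε′/ε″
  spectra.
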