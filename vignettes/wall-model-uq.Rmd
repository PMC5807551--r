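---
title: "Methods: wall-model uncertainty quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wall-model uncertainty quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modelling assumptions, parameter conventions,
numerical choices and known limitations of `hgowall`. It is the package's
own account of its methods; every number quoted here is computed by the
test suite or by `scripts/acceptance.R`, not asserted independently.

## Constitutive model and kinematics

The carotid segment is a thick-walled, incompressible tube of an isotropic
elastin matrix (neo-Hookean energy `c_elast * (I1 - 3)`) in parallel with
two helical collagen fibre families at ±β₀ to the circumferential
direction, each with the exponential fibre energy
`k1/k2 * (exp(k2 * (λ_f² - 1)²) - 1)`,
`λ_f² = cos²β₀ λ_θθ² + sin²β₀ λ_zz²`. Deformation is along principal axes
only (no shear, no torsion), and smooth-muscle tone, fibre dispersion and
viscoelasticity are outside the model class.

Residual stress is represented by opening-angle kinematics: the stress-free
configuration is an opened sector with opening angle α whose sector
subtends `2π − 2α`, giving the closure factor `k = 2π/(2π − 2α)` (2.25 for
the default α = 100°; this is the standard convention in the
opening-angle literature, and the fitted results proved insensitive to the
convention — refits with k from 1.0 to 3.0 move the error by < 2%
relative). A material point at unstressed radius `R` maps to
`r(R) = sqrt(r_i² + (R² − R_i²)/(k λ_zz))` with the axial pre-stretch
fixed at `λ_zz = 1.20` throughout loading, so the deformed cross-sectional
wall area `A_w` — computed from the measured diastolic outer diameter and
intima–media thickness as an annulus — is conserved at every pressure.
The unstressed outer radius closes the kinematics:
`R_o² = R_i² + k λ_zz A_w/π`.

Because the material is incompressible, the indeterminate hydrostatic
pressure is eliminated analytically: pressure and reduced axial force only
need the stress *differences*

```
P   = ∫ (σ_θθ − σ_rr)/r dr
F_z = π ∫ (2 σ_zz − σ_rr − σ_θθ) r dr
```

so absolute Cauchy stresses are never formed. Collagen carries no
tension-compression switch; instead `collagen_load_fraction()` asserts
`λ_f ≥ 1` at every quadrature node of the solved state (the condition holds
at all positive luminal pressures in the fitted configurations; an error is
raised if it ever fails rather than silently clipping).

Units are SI internally (Pa, m, N); mmHg, mm, µm and kPa appear only at
I/O boundaries with 1 mmHg = 133.322 Pa.

## Numerical choices

* **Quadrature**: fixed 40-point Gauss–Legendre across `[r_i, r_o]`. The
  integrand is smooth, so the rule is spectrally accurate; tests verify
  agreement with a 20 001-point trapezoid oracle to 1e-8 relative, and a
  thin-wall (Laplace-law) limit to 1%.
* **Inflation solve**: the pressure–radius relation is monotone over the
  physiological range, so `solve_inflation()` brackets the root in
  `[0.1 R_i, 10 R_o]`, uses `uniroot`, and polishes with secant steps to an
  absolute pressure tolerance of `1e-6 · max(P, 1 Pa)`. Overflowed trial
  states during bracketing are capped at a large finite pressure to keep
  the search monotone.
* **Optimiser**: bounded Levenberg–Marquardt (`minpack.lm::nls.lm`,
  `ftol = 1e-12`, `ptol = 1e-10`, at most 2000 evaluations per start) on
  the parameter vector `(c_elast [kPa], k1 [kPa], k2, R_i [mm])`, whose
  coordinates have comparable magnitudes. The two residual families are
  stacked with weights `sqrt(w_P/n_P)/P_p` and `sqrt(w_Fz/n_P)/F_norm`, so
  the squared norm is exactly the weighted total error
  `ε_T = w_P ε_P + w_Fz ε_F` (w_P = 10, w_Fz = 1, F target 0.5 N).
* **Start points**: the fitting problem has a stress-overflow region
  (large `k2`, small `R_i`) where the objective is a flat penalty plateau.
  Start points are therefore the deterministic log-space centre of the
  bound box plus `n_starts − 1` random points (log-uniform for `c_elast`
  and `k1`, whose bounds span several decades; uniform for `k2` and
  `R_i`), drawn once per configuration seed and reused for every sample.
  Fits whose best deviance remains on the plateau are flagged
  non-converged. All pipeline runs use 10 starts.
* **Fitting grid**: 50 points equally spaced in pressure over
  `[P_d − 15, P_s + 15] mmHg` (the validity range assumed for the
  exponential curve). The grid density is a free choice; refits with 25 or
  100 points move the well-identified parameters (`c_elast`, `k2`, `R_i`)
  by < 0.5%. The collagen scale `k1` is intrinsically ill-conditioned from
  in-vivo pressure ranges (its fitted spread spans decades) and moves by a
  few percent with the grid; the tests budget 5% for it.

## The virtual cohort (synthetic-data stage)

The cohort emulates repeated non-invasive measurements of one
group-averaged subject. For each of the five measured variables
(P_d 72 ± 3.0 mmHg, P_p 58 ± 3.1 mmHg, D_d 6.37 ± 0.22 mm,
ΔD 0.789 ± 0.035 mm, IMT 539 ± 40 µm; intra-subject SDs), the 95%
uncertainty domain of the mean of `N_rep = 3` repeats is
`mean ± 1.96 SD/√N_rep`. A 5-dimensional Sobol sequence (standard
direction numbers, Gray-code construction, `skip = 0`; the generator
reproduces the usual reference implementations bit-for-bit) fills the box
**uniformly** — deliberately heavier-tailed than the Gaussian that
motivates the box, i.e. a worst case; a truncated-Gaussian sampler is
available but off by default. Derived values are `P_s = P_d + P_p` and
`D_s = D_d + ΔD` with summands independent, which the tests verify through
variance additivity. Mean arterial pressure is taken as the standard
clinical estimate `P_m = P_d + P_p/3` (no definition is fixed by the study
conditions; this choice is configurable and recorded per sample).
Unphysical samples would be rejected with a logged count, but the default
domains sit far from the invariant boundaries and produce none.

What the generator does *not* emulate: between-subject variability,
correlations among measured variables, acquisition-specific artefacts
(echo tracking, cuff calibration) and pressure-diameter hysteresis. Tests
that pass on this cohort therefore validate noise *propagation* through
the fitting chain, not the measurement model itself.

Cohort-scale computations in the tests and the acceptance script use
250–256 samples with 10 starts each (about a minute of CPU); the medians
and percentile intervals are stable at this size because the uniform box
sampling is low-discrepancy.

## Sensitivity analysis

Each mechanical characteristic is regressed on a tensorised **Legendre**
polynomial basis over the five-dimensional uncertainty box, orthonormal
under the uniform sampling measure (a Hermite basis would be inconsistent
with the box sampling; matching the metamodel measure to the sampling
measure is what makes the variance decomposition exact). The total degree
is chosen adaptively: the lowest degree on a 2…8 ladder whose closed-form
leave-one-out `Q²` exceeds 0.99, otherwise the best model flagged
non-compliant. Main and total Sobol indices come from grouping squared
coefficients by multi-index support; an independent Saltelli/Jansen
pick-freeze estimator run on the metamodel itself must agree within three
Monte-Carlo standard errors (tested on additive, pure-interaction and
Ishigami functions, the latter against the closed-form variance
decomposition to 0.01).

## Simulated AGE-breaker treatment

Cross-link breaking is represented by scaling `k1` and `k2` by
`1 − reduction` (default 40%) in every fitted realisation, leaving
`c_elast` and `R_i` unchanged. Post-treatment diameters are re-solved from
the modified model at the *same* sampled diastolic and systolic pressures
(pressures are not re-sampled). Pre-treatment area compliance uses the
measured sampled diameters, post-treatment compliance the model-predicted
diameters — both conventions are recorded per realisation. Properties
enforced by tests: zero reduction is the identity of the whole stage;
collagen load bearing never increases under treatment at any pressure
level; compliance rises for every realisation.

## Distribution summaries

Medians and 25th–75th percentile intervals use the linear-interpolation
quantile convention (R type 7) — the endpoints at small n depend on this
choice, which is why it is fixed and documented. Kernel density estimates
are Gaussian with Silverman's rule-of-thumb bandwidth on a 512-point grid
spanning the data ± 3 bandwidths; mass conservation to 1e-3 and recovery
of a known normal density to 0.02 are tested.

## Known limitations and deviations from the published values

The package reproduces the published cohort-level results closely
(medians of `c_elast`, `k2`, collagen load bearing, the treatment effect
and compliance shift), but two groups of published numbers are **not**
reproduced, and the discrepancy is reported rather than tuned away:

1. **The representative single fit.** Fitting the group-means curve under
   the stated objective lands robustly (all starts, all grid densities,
   all kinematic conventions tried) at
   `c_elast ≈ 47.9 kPa, k1 ≈ 1.0 kPa, k2 ≈ 9.9` with a pressure error of
   ≈4.6% — whereas the published representative example reports
   `40.1 kPa / 6.9 kPa / 8.5` with a pressure error of 0.020%. Within this
   implementation no point of the bounded parameter space fits the
   exponential curve anywhere near that closely (the model family's best
   possible pressure error is ≈0.2% even with the axial-force term
   disabled), so the published example appears to depend on implementation
   details outside the printed equations. Notably, this package's
   group-means fit sits within a few percent of the published *cohort
   medians*, which is the behaviour expected of a near-additive map over a
   symmetric uncertainty box.
2. **The dominant sensitivity driver.** Because the fitted curve retains a
   structural residual, the fitted parameters respond mostly to the
   geometric inputs (diastolic diameter, IMT) and only weakly to the
   curve-shape input (distension). The implemented pipeline attributes
   `c_elast` variance mostly to IMT and `L_coll` variance mostly to `D_d`,
   while the published tables attribute both mostly to distension. The
   structural findings that do transfer: interactions are negligible
   (`S_T − S_i < 0.10` everywhere), the `Q² > 0.99` gate is met by low
   degrees, and the pressure variables are minor contributors.

Other limitations: no fibre dispersion, no smooth-muscle activity, no
viscoelasticity; the axial-force target (0.5 N) and weights are fixed
assumptions; area compliance from the group means evaluates to
0.1445 mm²/mmHg, which the source rounds to 0.15.
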