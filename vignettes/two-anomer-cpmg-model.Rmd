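---
title: "The two-anomer fast-exchange CPMG binding model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-anomer fast-exchange CPMG binding model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmgbind)
```

## Scope

`cpmgbind` estimates per-anomer dissociation constants and a shared
bound-state transverse relaxation rate from ligand-observed ¹⁹F CPMG
titrations of reducing sugars against a protein target, here motivated
by fluorinated 2-deoxy-D-glucose analogs binding hexokinase II. The
exact fitting formulas behind published per-compound parameter tables
of this kind are typically kept in supplementary material and are not
always available; the model in this package is therefore an independent
formulation of the standard population-weighted fast-exchange
treatment, extended to the coupled equilibrium of two anomers, and
should be read as such rather than as a transcription of any specific
published derivation.

## The physical model

Three timescale assumptions define the model.

1. **Fast exchange between free and bound ligand.** Binding kinetics
   are fast relative to relaxation, so each resonance relaxes at the
   population-weighted average rate
   \[
   R_{2,\mathrm{obs}} = (1 - p_b)\, R_{2,\mathrm{free}} +
     p_b\, R_{2,\mathrm{bound}},
   \]
   where \(p_b\) is the ligand-side bound fraction. No
   exchange-broadening term is included; intermediate-exchange
   (Carver–Richards) behaviour is out of scope.
2. **Slow anomerization.** Mutarotation is slow on the chemical-shift
   timescale, so the α and β anomers appear as separate signals and no
   relaxation transfer occurs between them. Each anomer pool is an
   independent competing species.
3. **1:1 binding at a single site.** Each anomer (and any competitor)
   binds the same site with its own dissociation constant. The bound
   ligand tumbles with the protein regardless of anomeric
   configuration, so one bound-state rate \(R_{\mathrm{bound}}\) is
   shared by both anomers. This mirrors how such results are tabulated
   (one bound rate per compound) and, together with free rates fixed
   from a protein-free reference sample, removes a fitting degeneracy.

With total protein \(P_{\mathrm{tot}}\) and species totals
\(L_{\mathrm{tot},i}\) with constants \(K_i\), the free protein
\(P_f\) solves

\[
P_f \Bigl(1 + \sum_i \frac{L_{\mathrm{tot},i}}{K_i + P_f}\Bigr)
  = P_{\mathrm{tot}},
\]

which is monotone in \(P_f\) on \([0, P_{\mathrm{tot}}]\) and so has a
unique non-negative root. Complexes follow as
\(P_f L_{\mathrm{tot},i} / (K_i + P_f)\) and each anomer's bound
fraction is \(P_f / (K_i + P_f)\).

## Units

Concentrations are mM (≡ mol·m⁻³) and rates s⁻¹ throughout.
Affinities of this magnitude are sometimes described loosely as
"micromolar-range" in prose; this package always works and reports on
the millimolar scale that the concentration series (0.25–6 mM ligand
at 0.01 mM protein) actually probes.

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `protein_total` | mM | 0.01 | the titration layout emulated |
| `ligand_totals` | mM | 0.25–6.0 (8 points) | id. |
| `reference_total` | mM | 2.0 | protein-free sample fixing the free rates |
| `delays` | s | 0.004–2.048 (8, ~geometric) | three-decade CPMG delay span |
| `anomer_fraction_alpha` | — | 0.4 | glucose-like α:β ≈ 40:60; an assumption, anomeric ratios are rarely reported |
| `r_free_alpha/beta` | s⁻¹ | 2.0 | typical small-molecule ¹⁹F R₂; in analyses of real data these come from the reference sample, not a default |
| `noise_sigma` | — / s⁻¹ | 0.02 (relative) | see below |
| `weighted` | — | FALSE | unweighted least squares, as in a default-settings fit; inverse-variance weights available when errors are supplied |
| `fit_r_free` | — | FALSE | free rates fixed from the reference sample by default |

**Noise model.** True experimental noise levels for such titrations are
rarely published. The generator's default is additive Gaussian noise on
rates with σ equal to 2% of the dynamic range of the noiseless rates of
the design (reference rates included). At that level the
recovered-parameter scatter across replicates is comparable in relative
magnitude (≈ 20–25%) to standard errors typically reported for fits of
this kind, which is what the default is calibrated to emulate; it is a
reconstruction, not a measured value. `noise_type = "absolute"` gives σ
directly in s⁻¹.

## What the generator emulates — and what it does not

`simulate_titration()` reproduces the sampling layout (nine samples:
eight protein + ligand, one ligand-only), the two-anomer split, the
fast-exchange forward model, and seeded Gaussian noise; replicate *r*
draws from a deterministic child stream of the master seed
(`seed + 7919·r`), so replicate sets extend without reshuffling.
Optionally it emits raw intensity decays
\(I(t) = I_0 e^{-R_2 t}\) with multiplicative noise at the design's
delay schedule. It does **not** emulate spectrometer artifacts —
baseline roll, phasing error, field drift, peak overlap, temperature
gradients — nor ligand depletion by slow anomer re-equilibration.
Passing recovery tests on these simulations therefore demonstrates
correctness of the estimator under the model's own assumptions, not
robustness to real-spectrum pathologies.

## Fitting and numerical choices

* **Equilibrium root.** Safeguarded Newton on the monotone concave
  mass-balance function, started at \(P_f = P_{\mathrm{tot}}\),
  iterated to a residual below \(10^{-13} P_{\mathrm{tot}}\) (Newton
  converges quadratically, so targeting well below the guaranteed
  \(10^{-10}\) relative mass balance costs nothing); any point not
  meeting tolerance falls back to bracketed root finding on
  \([0, P_{\mathrm{tot}}]\). Species with `kd = Inf` are dropped
  exactly, so a non-binding competitor reproduces the competitor-free
  prediction bit for bit.
* **Decay fitting.** Log-linear regression of log-intensity initializes
  a Levenberg–Marquardt fit of \(I_0 e^{-R_2 t}\); a final Newton
  polish on the profiled one-parameter objective (with \(I_0\)
  eliminated in closed form) drives the estimate to machine precision,
  making it exactly invariant to intensity rescaling. No baseline
  term by default — CPMG decays to zero — with an optional offset for
  real-data pathologies. Non-decaying data yield a flagged estimate,
  never a silent success.
* **Titration fit.** Levenberg–Marquardt on
  \((K_\alpha, K_\beta, R_{\mathrm{bound}})\) under positivity bounds,
  from a multistart grid: K starts \(\{0.1, 0.5, 1, 2, 5\}\) mM crossed
  with \(R_{\mathrm{bound}}\) starts at \(\{2, 10, 50\}\times\) the
  largest observed rate. Best final objective wins; ties break to the
  smallest \(K_\alpha\). Records are put in canonical order first, so
  the fit is exactly permutation invariant. Standard errors come from
  the residual-scaled curvature at the optimum; a parameter pinned at a
  bound raises an identifiability warning.
* **Competition profiling.** With probe parameters fixed, the residual
  sum of squares is profiled over a wide log-spaced grid of the
  competitor's effective K_d. The verdict is `"bounded"` only if,
  *within the tested competitor-concentration window*, the profile
  rises at least 2 units above its minimum on both sides — 2 units on
  the scale of the residual variance at the minimum, the usual ≈95%
  profile-likelihood cutoff for one parameter. The window restriction
  encodes that a concentration series can only resolve dissociation
  constants commensurate with the concentrations actually tested; a
  weak binder yields a flat in-window profile and is reported as a
  lower bound on K_d, never as a point estimate.
* **IC₅₀.** A monotone-decreasing four-parameter logistic is fitted and
  the IC₅₀ is read as the concentration where the fitted curve crosses
  50% of control — not the curve's midpoint, which differs whenever the
  asymptotes are not exactly 100% and 0%. Published coarse IC₅₀ values
  on such assays often look dose-grid snapped, so a `"snapped"`
  reporting mode (nearest tested dose) is provided alongside the
  default `"fitted"` mode; no claim is made about which convention any
  particular published table used. A curve that never crosses 50%
  within the tested range is flagged as extrapolated.

## Degenerate inputs

Zero protein gives free rates exactly; a zero-concentration anomer pool
(anomeric fraction 1) is reported at its free rate; an all-zero
competitor series is an explicit error (no information about K_d);
fewer than 4 distinct titration concentrations, a missing anomer, or a
non-positive control mean are rejected with named errors; malformed
table rows are reported with their file line numbers.

## Design choices that were genuinely open

* **Competitor anomerization.** The competitor is one effective species
  with one effective K_d. Unlabelled competitors anomerize too, but
  only the probe is observed, so per-anomer competitor constants are
  not identifiable from these data; attempting them would only re-open
  the degeneracy the probe-side simplifications close.
* **Free rates fixed, not co-fitted.** The protein-free reference
  sample measures them directly; co-fitting (available via
  `fit_r_free = TRUE`) trades that measurement for two extra weakly
  identified parameters.
* **Shared bound rate.** One \(R_{\mathrm{bound}}\) per compound, both
  because bound-state tumbling is anomer independent to first order and
  because per-anomer bound rates are strongly confounded with the
  dissociation constants at low protein occupancy.
* **Unweighted default.** Matches a default-settings non-linear fit;
  weighting is principled when per-point errors exist, so it is an
  option, not the default.

## Uncertainty honesty

Standard errors are asymptotic (residual-scaled curvature). For this
design the \(K\)–\(R_{\mathrm{bound}}\) pair is substantially
correlated at low protein occupancy, so nominal ±1 SE intervals should
be expected to cover the truth somewhat below the Gaussian nominal 68%;
treat single-dataset standard errors as indicative and prefer replicate
simulation (as the acceptance script does) when calibrated uncertainty
matters.

## Problem sizes used in the shipped checks

The package's own verification uses: 1000 random equilibrium instances
against an independent damped fixed-point oracle; a noiseless
end-to-end recovery grid spanning \(K \in [0.1, 5]\) mM and
\(R_{\mathrm{bound}} \in [500, 5000]\) s⁻¹; 20 random instances against
an exhaustive 21³ coarse-grid search; and 200-replicate Monte-Carlo
recovery runs per compound at the default design. These sizes were
chosen so the full suite runs comfortably on a laptop while leaving the
Monte-Carlo standard error of the recovered means an order of magnitude
below the recovery tolerances.

## Known limitations

Single-site 1:1 binding only (no ternary complexes or allosteric
coupling); no intermediate-exchange lineshape physics; no spectral
processing (the input is peak intensities or rates, not FIDs); the
competitor model is deliberately effective-single-species; IC₅₀ and
percent-of-control summaries implement the standard formulas only, with
no plate-effect or edge-well corrections.
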