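---
title: "Methods: binding models, potency, helicity and library analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding models, potency, helicity and library analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixscan)
```

helixscan analyzes stapled-peptide SAR campaigns against the p53–Mdm2
interaction. This vignette documents the models, their assumptions, the
defaults and why they were chosen, the numerical choices, and the known
limitations. Everything quantitative stated here is computed by the test
suite or the acceptance script; nothing is quoted from external analyses.

## Equilibrium binding models

### Direct 1:1 titration

A fluorescent tracer at fixed total concentration $L_t$ is titrated with
protein ($P_t$). Assuming a single site and equilibrium, the bound tracer
concentration $b$ satisfies $K_d\,b = (L_t - b)(P_t - b)$, and the
anisotropy is the linear interpolation $r = r_0 + (r_b - r_0)\,b/L_t$
between the free-tracer ($r_0$) and complex ($r_b$) anisotropies. The
implementation uses the cancellation-free form
$b/L_t = 2P_t\big/\big(S + \sqrt{S^2 - 4L_tP_t}\big)$ with
$S = K_d + L_t + P_t$. The linear-interpolation assumption requires the
tracer's fluorescence lifetime and quantum yield to be binding-independent;
the assay checks this by comparing the titration start point with the free
tracer, and `anisotropy_direct()` warns when $r_b < r_0$.

The default assay constants throughout are those of the competitive FP
setup the package models: tracer $K_{d1} = 13.0$ nM, $L_{st} = 50$ nM
tracer, $P_t = 250$ nM protein. At these constants the bound tracer
fraction is 0.9398 (computed independently by bisection and by the closed
form), so the competition assay starts from a nearly saturated complex —
which is what makes displacement interpretable.

### Competitive displacement: the exact cubic solution

With an unlabeled competitor ($K_{d2}$, total $L_t$) added to the
tracer–protein mixture, free protein $p$ satisfies

$$p + \frac{L_{st}\,p}{p + K_{d1}} + \frac{L_t\,p}{p + K_{d2}} = P_t,$$

equivalent to the monic cubic $p^3 + d p^2 + e p + f = 0$ with
$d = K_{d1}+K_{d2}+L_{st}+L_t-P_t$,
$e = K_{d1}(L_t-P_t) + K_{d2}(L_{st}-P_t) + K_{d1}K_{d2}$,
$f = -K_{d1}K_{d2}P_t$. All three roots are real for physical inputs and
the physical one is obtained trigonometrically
($\theta = \arccos[(-2d^3+9de-27f)/(2\sqrt{(d^2-3e)^3})]$); the bound
tracer fraction is $p/(p+K_{d1})$.

Numerical choices:

* The $\arccos$ argument is clamped when within $10^{-9}$ of $\pm 1$;
  beyond that it is an error carrying the intermediates, distinguishing
  round-off from invalid inputs.
* The trigonometric roots lose digits in two regimes: when the physical
  root is orders of magnitude below $|d|$ (cancellation between
  $2\sqrt{d^2-3e}\cos(\theta/3)$ and $d$), and when $\theta \to 0,\pi$
  (angle sensitivity, e.g. an effectively non-binding competitor with
  $K_{d2} \sim 10^{12}$ nM). The implementation therefore also deflates the
  well-conditioned dominant root and solves the remaining quadratic in its
  stable form, selects the candidate satisfying the protein mass balance,
  and finishes with Newton steps on the cubic itself. The result agrees
  with an independent bracketed mass-balance solver
  (`solve_equilibrium_numeric()`, bisection plus Newton polish, residual
  $\le 10^{-9} P_t$) to better than $10^{-6}$ relative over $10^4$ random
  draws spanning seven decades of both $K_d$s — in practice the worst
  observed deviation is near machine precision.
* The assay validity condition $P_t > L_{st}$ is a warning, not an error,
  so diagnostic exploration of degenerate designs remains possible; the
  fitting functions enforce it.

### Fitting

`fit_direct()` and `fit_competition()` minimize pooled replicate residuals
by Levenberg–Marquardt (`minpack.lm`), with $\log_{10} K_d$ as the free
parameter (positivity by construction) multi-started 1.5 decades either
side of a data-driven initial value (the titrant concentration at
half-range) to avoid local minima on weak binders. $r_0$ and $r_b$ float
by default and may be fixed. Standard errors come from the local
curvature; the $K_d$ SE is delta-method transformed from the log scale.
Non-convergence and degenerate inputs (flat curves, fewer than 5 points)
return `converged = FALSE`, never an exception.

Whether the original competition analysis floated or fixed the anisotropy
end points is not documented; both modes are provided. For the weak-binder
calibration scenario ($K_{d2} = 3600$ nM titrated to 50 µM) the curve
reaches only partial displacement, so the lower asymptote is unidentifiable
from the data alone and floating it inflates the $K_{d2}$ error severely
(Monte-Carlo coverage of a ±20% band roughly halves). Since both end
points are directly measured in the assay — $r_0$ from the free tracer,
$r_b$ from the pre-displacement plateau — the calibration scenario anchors
them at their known values. This is the standard practice for
partial-displacement fits and is a design choice made on identifiability
grounds, not a tuning step.

Monte-Carlo calibration (200 seeds, $\sigma_r = 0.005$, 12-point grids in
triplicate) puts ≥ 85% of direct-fit $K_d$ estimates within ±15% of the
truth at the 13 nM/50 nM depletion-limited design, and ≥ 95% of
anchored weak-binder $K_{d2}$ estimates within ±20%; the acceptance tests
assert exactly these calibrated coverages.

## Dose–response potency

Reporter and LDH signals are affinely normalized to assay-defined 0/100%
controls; values outside $[0, 100]$ are reported as-is (negative values
flagged, never clipped). The potency model is a four-parameter logistic on
$\log_{10}$ dose — the field standard for reporter assays; the source
analysis does not state its curve model, so the 4PL is a documented package
choice. Censoring: any of (i) non-convergence, (ii) fitted EC$_{50}$ above
the top tested dose, (iii) a response window below 20% of the control
range, yields a right-censored `">max_tested"` result carrying no
hill/top/bottom claims. The 50 µM bound matches the library convention for
inactive entries. Replicate potencies aggregate as geometric means,
helicities as arithmetic means.

The cell/target ratio $1000 \cdot \mathrm{EC}_{50}(\mu M)/K_d(nM)$ is
rounded half-up to the nearest integer, the convention that reproduces the
audited printed rows exactly (e.g. template 29, linear parent 777, the
censored inactive row ">8"). Eleven of the fifty printed ratios differ by
1–2 units from recomputation out of their own printed inputs — presumably
computed from unrounded instrument values; `ratio_lint()` surfaces these
rather than forcing agreement.

## CD helicity

`ellipticity_to_mre()` applies
$\mathrm{MRE} = \theta_{mdeg}/(10\,c_M\,\ell_{cm}\,n_{res})$. The residue
count defaults to the cap-exclusive core count (14 for the stapled
template); whether cap groups were counted in the original conversion is
undocumented, so cap-inclusive counting is available via
`residue_count(p, include_caps = TRUE)`.

The proprietary neural-network deconvolution used for the printed
helicities is not replicated; printed helicity columns are treated as
input data. Two transparent estimators are provided:

* **Single wavelength:** $f_H = (\mathrm{MRE}_{222} - \theta_{coil}) /
  (\theta_{helix}^{\infty}(1 - k/n) - \theta_{coil})$ with the
  field-standard limiting values $\theta_{helix}^{\infty} = -39500$,
  $k = 2.57$, $\theta_{coil} = -3000$ deg cm² dmol⁻¹, all overridable.
  Out-of-range estimates are clipped to $[0,1]$ with the raw value
  retained.
* **Basis fit:** non-negative least squares over packaged helix/coil/sheet
  reference shapes constrained to sum to one, solved exactly by
  constraint elimination with an active set (the basis has three columns,
  so the active-set loop terminates in at most two drops). The helix
  column is length-corrected by $(1-k/n)$ so the coefficient matches the
  single-wavelength scale.

The packaged basis shapes are synthetic parameterizations of the canonical
band structure (helix: 208/222 nm double minimum, positive ~192 nm band;
coil: deep ~198 nm minimum; sheet: ~217 nm minimum, positive ~196 nm band),
anchored to the limiting constants above. They are adequate for estimator
validation and round-trip testing; they are not measured reference spectra,
and per-peptide reproduction of printed helicities is out of scope anyway
because the per-sample re-measured concentrations are unavailable.

## Library analytics

`series_helicity_summary()` reproduces the printed alanine-scan range
(27.6–53.3%, mean 40.8 over the nine measurable rows). Fold-changes vs the
parent quantify scan effects (the three interfacial positions degrade
binding ~10–200-fold). `correlate_lipophilicity()` regresses the
cell/target ratio on HPLC-LogD or ALogP; the default response is
$\log_{10}$(ratio) because ratios span 2–777 and a raw-ratio fit would be
dominated by the least permeable rows — the original figure's axis
transform is unstated, so raw-ratio mode is retained. Censored ratios are
excluded and counted. $R^2$ is the squared Pearson correlation; a
zero-variance response is reported as $R^2 = 0$ and flagged degenerate.
The printed correlation strengths are not reproduction targets because the
underlying per-peptide lipophilicity values are unpublished; the
correlation stage is validated by synthetic recovery instead (below).

ALogP is consumed, never computed: descriptor calculation for non-natural
residues is out of scope.

## Synthetic data: what it emulates, and what it does not

The generators produce every input class with known ground truth under the
study's assay conditions: titrations at the 13/50/250 nM constants with
$\sigma_r = 0.005$ Gaussian anisotropy noise in triplicate (12-point
log-spaced grids — the exact instrument grids are undocumented, so the
generator exposes them as parameters); dose–response on a 10-point
0.01–50 µM grid with 5% noise; CD spectra at 1 mM, 0.2 cm, 190–300 nm;
libraries of 50 peptides with $K_d$ log-uniform over the printed 5–5000 nM
span and a planted law
$\log_{10}(\mathrm{ratio}) = a + b\,\mathrm{logD} + \varepsilon$. The
default law ($b = -0.6$, $\mathrm{logD} \sim N(2.5, 1)$,
$\sigma = 0.6$) makes lipophilicity explain half the log-ratio variance,
$R^2_{exp} = b^2\sigma_x^2/(b^2\sigma_x^2 + \sigma^2) = 0.5$, the strength
of the observed library correlation. Each generator derives a decoupled
stream from the global seed (`derive_seed()`), so outputs are
bit-reproducible and insensitive to call order.

The expected-$R^2$ oracle assumes no censoring-induced selection, so the
recovery test draws $K_d$ from 10–100 nM, where fewer than ~4% of rows
censor; under the full 5–5000 nM default about a third of rows censor and
the realized $R^2$ is attenuated accordingly — a real feature of censored
SAR tables, not a defect of the generator.

Not simulated: plate drift, inner-filter effects, serum-shift kinetics,
instrument-specific artifacts, and any structural chemistry. Passing the
round-trip and recovery tests therefore demonstrates correctness of the
estimators under their own noise model, not robustness to every artifact
of real instrument data.

## Problem sizes

The shipped tests and acceptance script use $10^4$ random draws for the
closed-form-vs-oracle certification, 200 Monte-Carlo seeds per recovery
calibration, and 50-row synthetic libraries — sizes at which all
calibration statistics are stable to well within their asserted margins.

## Known limitations

* The notation parser models token identity only: no chemistry, no 3D
  structure, no conformers.
* The binding models assume equilibrium, a single site, and no
  ligand–tracer interaction (the baseline diagnostic flags the latter).
* Kinetic (SPR) and calorimetric (ITC) analyses are out of scope; their
  $K_d$s are consumed as inputs where present.
* One printed scan label names position 6 while its substitution sits in
  column 7; the parser trusts the sequence columns and `lint_scan_label()`
  reports the mismatch without correcting it.
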