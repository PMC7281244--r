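---
title: "Models and methods behind fibrilr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fibrilr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilr)
```

# Scope

`fibrilr` implements the quantitative analysis used to characterise
amyloid fibrillation of two model proteins — hen egg-white lysozyme and
bovine insulin — under varying trehalose and NaCl content, from three
complementary observables:

* **SAXS** (small-angle X-ray scattering): absolute-scale forward models
  for the species populating a fibrillating solution and model-free
  Guinier/Kratky analysis;
* **Congo Red UV/Vis absorbance**: the 538/505 nm bound/free dye ratio
  as a semi-quantitative β-structure proxy, and its kinetics;
* **far-UV CD**: band-shape classification of the secondary-structure
  state.

No experimental curves from the original study are publicly available,
so the package ships seeded generators that emulate each instrument's
output under every studied solvent condition; all statistical claims in
the test suite are made against these generators, at stated sizes.

# SAXS forward models

Units are fixed package-wide: momentum transfer $Q$ in
$\mathrm{\AA}^{-1}$, lengths in $\mathrm{\AA}$, intensities
$d\Sigma/d\Omega$ in $\mathrm{cm}^{-1}$. Every species carries a `scale`
equal to its forward intensity: number density × squared contrast ×
squared volume, absorbed into one parameter. Mixtures are strictly
dilute — intensities add, and a flat background closes the model.

## Cylinders (mature fibrils)

The orientation average
$P(Q)=\int_0^1 \left[\frac{2J_1(QR\sqrt{1-u^2})}{QR\sqrt{1-u^2}}
\cdot \mathrm{sinc}\frac{QLu}{2}\right]^2 du$
is computed by Gauss–Legendre quadrature under the cubic substitution
$u=t^3$, which concentrates nodes in the sharp longitudinal peak near
$u=0$ of long cylinders. The node count starts at 64 and doubles until
the peak-normalised change is below $10^{-4}$ (the peak-normalised
criterion keeps the adaptive rule from chasing the deep form-factor
zeros, where any fixed-grid scheme loses relative accuracy). The disc
amplitude $2J_1(x)/x$ is served from a 0.005-spaced lookup table with
linear interpolation (|error| < 5×10⁻⁶), which is what makes the
mixture fits affordable in pure R; the quadrature is validated against a
brute-force trapezoid oracle at much higher resolution in the test
suite.

Radius polydispersity uses a Gaussian distribution truncated at $R>0$
and at ±3 standard deviations on a fixed 21-node Gauss–Legendre grid,
renormalised; a Schulz distribution is available as an option. The "±
per-cent" language used for the insulin fibrils reads naturally as a
symmetric spread, hence the Gaussian default. Population averaging is
intensity-weighted ($R^4$, volume squared at fixed length) so that the
forward intensity still equals `scale`.

## Worm-like chains (disordered species)

`wormlike_intensity()` implements a parametrised coil–rod crossover of
the Pedersen–Schurtenberger type, without excluded-volume corrections
(which variant the original analysis used is not stated; the
no-excluded-volume branch is the simpler and sufficient choice for
denatured-protein cross-radius work). The low-$Q$ branch is the Debye
coil function evaluated at the Benoit–Doty radius of gyration of a
worm-like chain; the high-$Q$ branch is the stiff-rod asymptote
$\pi/(QL) + 2/(3Q^2Lb)$; a $\tanh$ bridge in $u=Qb$ joins them at their
intersection $u^\ast=(12-\tfrac23)/\pi\approx3.61$, making the crossover
continuous. The circular cross section multiplies the result by
$[2J_1(QR_c^{geo})/QR_c^{geo}]^2$.

Two conventions circulate for a chain's "cross radius": the geometric
radius of the circular cross section and the cross-sectional radius of
gyration ($R^{geo}/\sqrt2$). The package parameter `cross_radius` is the
geometric radius, and summaries report both. The `aggregation_number` is
carried as metadata only — how it maps onto the fitted scale is not
defined operationally in the source analysis, so it is deliberately not
a fit constraint.

## Atomic structures (native monomer)

`debye_intensity_from_structure()` evaluates the Debye double sum
through a weighted pair-distance histogram (0.5 Å bins). Scattering
factors are per-element electron counts minus the displaced-solvent term
(Fraser–MacRae–Suzuki volumes, bulk water at 0.334 e⁻/Å³), constant in
$Q$ — a small-angle approximation that is excellent below
$Q \approx 0.3\,\mathrm{\AA}^{-1}$. X-ray structures carry no
hydrogens, so average bonded-hydrogen counts are merged into the heavy
atoms. The hydration shell follows the dummy-scatterer idea: candidates
on each atom's rolling-probe sphere (probe 1.4 Å), buried points
discarded, survivors thinned to a 3 Å surface grid, each carrying
`shell_contrast × grid² × thickness` excess electrons with a default
contrast of +0.03 e⁻/Å³. All shell parameters are overridable. With the
defaults, the hen egg-white lysozyme crystal structure shipped with
bio3d (PDB entry 1HEL — the same protein as the 6LYZ entry used in the
original fits) gives a Guinier radius of ≈17 Å, inside the 16 ± 1.5 Å
band expected for the monomer.

# Model-free analysis

## Guinier and rod-like Guinier

Both fits are weighted linear regressions in transformed coordinates
(globular: $\ln I$ vs $Q^2$, slope $-R_g^2/3$; rod: $\ln QI$ vs $Q^2$,
slope $-R_c^2/2$), with log-space weights $(I/\sigma)^2$ when
uncertainties are present. The fit window is found by a damped
fixed-point iteration on the size so that $QR_g \le 1.3$ (globular) or
$QR_c \le 1.0$ (rod) at convergence — the conventional validity limits;
the source analysis states neither, and both are overridable. Two
numerical guards matter in practice:

* if the iteration oscillates between two windows, the wider window
  wins (a stated tie-break); the damping makes this rare;
* after convergence, leading low-$Q$ points that droop systematically
  below the line (most negative residual, beyond 1.5× the RMS) are
  trimmed one at a time. For rods this is the region $QL \lesssim 10$
  where the $1/Q$ regime is not yet reached; without the trim the
  77 Å cross section of the mature-fibril family comes out ~3% low.

A curve with no convergent window — e.g. a mature fibril suspension fed
to the *globular* fit — raises an explicit "no Guinier regime" error;
this failure is itself the diagnostic that the particles are not
globular.

## Two-population rod decomposition

Mature fibrils (large $R_c$) and protofibrils (small $R_c$) are
separated sequentially: fit the large population in its low-$Q$ window,
subtract its extrapolated $\frac{1}{Q}e^{-Q^2R_c^2/2}$ contribution,
fit the small population above that window (residuals below 3σ are
masked first). Three practical details matter:

* At 1:1 forward intensities a naive low-$Q$ fit returns a ~25% biased
  average of the two radii, so the subtract-and-refit pass is
  alternated; and because a rod's true cross-section form factor decays
  much faster than its Guinier Gaussian, the large population's
  *extrapolation beyond its own window* must never be subtracted — the
  small population is instead fitted on the original curve beyond the
  large one's decay ($QR_c^{large} \gtrsim 2.5$).
* Convergence is a joint weighted fit of
  $\ln(QI) = \ln[A_1 P_c(QR_{c,1}) + A_2 P_c(QR_{c,2})]$ over the union
  of the two validity windows, where
  $\ln P_c(u) = -u^2/2 - u^4/48 - u^6/576$ is the series of the uniform
  circular cross section (the band between the windows, where the large
  population is beyond its Guinier regime but not yet negligible, is
  excluded; whether its series tail still enters the high-$Q$ band is
  decided by residual score). The size ordering is built into the
  parametrisation, and several seeds — the sequential pair plus
  tail-anchored candidates — guard against collapsed starts.
* Two families are reported as distinct only when their radii differ by
  ≥1.4× and both carry ≥1% of the forward intensity; otherwise the
  result degrades gracefully to a single-population fit.

On the 1:1 mixture of 108.9 Å and 42.4 Å cylinders the decomposition
recovers 77 and 30 Å within 10% (with or without 1% counting noise),
and a single-population input flags the second fit as not detected. The
method's resolution limit sits near a cross-section ratio of ~2.4: for
more similar families the two windows overlap irreducibly and recovery
degrades to the 10–20% level — closely spaced families are a job for
the full-curve mixture fit, not for sequential Guinier analysis.

## Kratky classification

`kratky_shape_score()` labels $Q^2I(Q)$ curves by where their high-$Q$
tail (last 20% of points) sits relative to the global maximum: `bell`
(tail below 50% of an interior maximum — compact globular), `plateau`
(tail flat within ±15% of its own mean — flexible chains), `rising`
otherwise. The score $1-\mathrm{tail}/\mathrm{max}$ makes the bell/
plateau distinction continuous.

# Mixture fitting

`fit_mixture()` minimises
$\chi^2=\sum_i[(I_i - I_{model}(Q_i))/\sigma_i]^2$ with bounded
Levenberg–Marquardt. Because the objective is multi-modal in the
geometric parameters, the optimiser restarts from seeded Latin-hypercube
points across the parameter box (default 8 starts; reproducibility
demands an explicit, seeded strategy). Uncertainties come from the
inverse Gauss–Newton curvature scaled by the reduced $\chi^2$;
`bootstrap_uncertainties()` cross-checks them by residual resampling
(deterministic per seed, and required to agree within a factor of ~2 on
well-conditioned fits). Parameters that finish on a bound are flagged.

Species "fractions" are defined as shares of total forward intensity
$I(0)$ — the source percentages are not defined operationally (number,
volume and intensity fractions all circulate), and the forward-intensity
share is the quantity the fit actually determines. `compare_models()`
ranks specifications by $\chi^2 + 2k$, an Akaike-style penalty on the
chi-square scale.

In realistic pipelines the cylinder radius is initialised from a
rod-like Guinier pre-analysis of the same curve ($R_0=\sqrt2 R_c$); the
recovery simulations in the test suite do exactly that, which is why
two optimisation starts suffice there.

# Congo Red analysis

`beta_ratio()` interpolates the composite spectrum linearly at exactly
538 and 505 nm (grids rarely contain them) and reports the raw ratio —
not rescaled — as the kinetic observable. Its license as a
β-structure proxy is monotonicity: on two-band spectra the ratio is a
strictly increasing function of the bound-dye fraction, which the test
suite verifies across the full sweep. The bound-band centre is a
parameter (the bound maximum is quoted both at ~538 and ~540 nm;
evaluation defaults to 538 nm, generation centres the band at 540 nm).

`area_ratio()` fits two Gaussian bands (centres initialised at 505 and
540 nm, widths free) and compares the bound/free **area** ratio with the
bound/free **fitted peak intensity** ratio — the equivalence that was
verified experimentally before adopting the cheap intensity statistic.
For the synthetic generator both CR bands use a 50 nm FWHM: equal
widths are exactly the condition under which band areas and band
amplitudes agree, i.e. the generator is built to satisfy the observed
equivalence; the strong overlap still produces the broad composite
signal seen in partially fibrillated samples. (An earlier draft with
45/55 nm widths reproduces the composite shape equally well but breaks
the area/intensity equivalence by a systematic 22% — incompatible with
the validation the ratio statistic rests on.)

Replicate handling mirrors the experimental protocol: at least nine
replicas per condition, with only means and standard errors propagated.

# CD analysis

Spectra are baseline-subtracted and smoothed with a natural smoothing
spline (`stats::smooth.spline`, strength = `spar`, 0 disables).
`locate_minima()` keeps negative local minima whose topographic
prominence exceeds 5% of the deepest one (shoulder suppression);
`classify_state()` is window-based: `native_like` needs minima in both
[204, 212] and [218, 226] nm, `beta_rich` exactly one minimum in
[210, 222] nm. The score is the depth fraction carried by the
qualifying minima, making the labels invariant under rescaling (the
experimental curves are "scaled for clarity", so absolute millidegree
comparisons are out of reach by design). Synthetic spectra combine
Gaussian basis bands with the canonical α (208/222), β (215) and coil
(198 nm) signatures; along a linear native→β interpolation the label
switches exactly once.

# Kinetics

The β-ratio time courses are fitted with a 4-parameter logistic — the
standard amyloid-kinetics convention; the source describes the
lag/elongation/plateau phases qualitatively but fits no model. The lag
uses the tangent-intercept convention $t_{lag}=t_{1/2}-2/k$, floored at
0. Traces that never rise above 5% of their scale are not fitted at all
(an unidentifiable sigmoid) but reported flat-censored; traces whose
last point sits below 90% of the fitted plateau, or whose midpoint lies
beyond the data, are censored too. `compare_conditions()` labels a
condition **blocked** when it is censored (or shows <5% of the
reference's signal rise) while sitting below 20% of the reference
plateau — the operational form of "fibrillation almost blocked".

Note that the CR ratio is a convex transform of the bound fraction, so
the apparent lag of a ratio trace is systematically later than the lag
of the underlying bound-fraction trajectory; recovery claims in the
tests therefore compare noisy fits against the fit of the noise-free
ratio trace, which is the estimand the instrument actually observes.

# Synthetic data and the scenario table

The per-condition kinetic parameters live in a shipped CSV
(`inst/extdata/scenario_table.csv`), not in code, so the encoded
qualitative orderings are auditable: NaCl shortens the lag (65 °C, pH
~2 protocols); trehalose without salt blocks lysozyme fibrillation
(plateau fraction 0.01) and delays insulin (midpoint 130→290 min,
i.e. tangent lag 80→240 min) while lowering its final ratio plateau by
10% (bound-fraction plateau 0.864 vs 0.90 — the 10% is applied to the
*measured ratio*, the quantity plotted in the original kinetics
figures); with salt present trehalose's effect collapses to a modest
slowdown. SAXS noise follows the counting-statistics shape
$\sigma_i = noise\sqrt{I_i\,\Delta Q_i}$ and is verified to be
calibrated ($\chi^2$ per point ≈ 1). The six end-state SAXS fixtures
(native lysozyme ± trehalose from the 1HEL structure, differing only in
scale — trehalose only changes the solvent contrast; fibrillated
lysozyme, cylinder R = 40 Å ≈20% polydisperse + disordered chains;
lysozyme+trehalose, two worm-like species with cross radii 9.5 and
15.8 Å; fibrillated insulin, cylinders 38 Å/30% + minor 20 Å chains;
insulin+trehalose, 85% disordered + wider 60 Å cylinders) regenerate
bit-identically from a seed, with a JSON manifest of all generating
parameters. Fibril lengths are nominal (L = 2000 Å ≫ the probed
$1/Q$ range): no cylinder length was ever reported, and only
cross-sectional quantities are meaningful.

What the generators deliberately do **not** emulate: interparticle
interference (all models are dilute-limit), radiation damage, detector
geometry/2D reduction, absolute-intensity calibration against a protein
standard, the pH-shift chemistry of the CR assay, and trehalose's
physical contrast mechanism beyond a scalar scale change. Passing tests
therefore demonstrate correctness of the estimators under the stated
noise model, not robustness to those real-data effects.

# Problem sizes and tolerances in the test suite

Deterministic desk-scale checks use 120-point noise-free curves. The
recovery studies use 50 seeded replicates per end-state scenario on
70-point curves with counting noise at 2% scale; the cylinder fits are
staged (radius and scales first at a nominal 25% polydispersity —
radius and spread trade off strongly enough that releasing both at once
can park the optimiser at the spread bound — then everything released),
with the radius initialised from a rod-like Guinier pre-analysis and
two optimisation starts. Claims are made on medians, with 10%
tolerance on cylinder radii and ±5 points on dominant fractions, and
20% on the worm-like cross radii — that fit is weakly determined, a
limitation inherited from the underlying two-species disordered model
itself. Guinier unbiasedness uses 200 replicates at 1% noise; noise
calibration 500 replicates; kinetic lag recovery 30–100 replicated
traces of 9 spectra per time point. These sizes are the package's
standing choices and are what the documented tolerances were verified
at.

# Known limitations

* The tanh-bridged worm-like chain is accurate for $L/b \gtrsim 4$ and
  away from the crossover by construction; within the crossover region
  it is a smooth interpolation, not the exact Pedersen–Schurtenberger
  numerical parametrisation (differences are at the few-percent level,
  comparable to the excluded-volume effects both variants neglect).
* Constant atomic scattering factors limit the Debye model to the
  small-angle regime; wide-angle use would need $Q$-dependent form
  factors.
* The two-population rod decomposition assumes exactly two rod
  families; three or more merge into effective radii.
* Fraction estimates are forward-intensity shares; converting them to
  molar or mass fractions requires volumes and contrasts that the
  one-parameter `scale` deliberately absorbs.
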