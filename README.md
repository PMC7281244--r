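# fibrilr

Quantitative analysis of amyloid fibrillation from solution scattering
and optical spectroscopy, for structural biologists studying how
cosolutes (here: the osmolyte trehalose, against varying NaCl ionic
strength) change the aggregation of model proteins — hen egg-white
lysozyme and bovine insulin — into β-sheet-rich fibrils.

The package provides, in one coherent toolchain:

* **SAXS forward models** on absolute scale (cm⁻¹): rigid cylinders
  with Gaussian/Schulz radius polydispersity (mature fibrils),
  Pedersen–Schurtenberger-type worm-like chains (disordered/unfolded
  protein), uniform spheres, and atomic structures evaluated through the
  Debye formula with a rolling-probe hydration shell of dummy
  scatterers; dilute-limit mixtures with flat background.
* **Model-free size analysis**: classical Guinier
  (ln I = ln I₀ − Q²Rg²/3, window Q·Rg ≤ 1.3), rod-like (cross-sectional)
  Guinier (ln QI = ln I₀ − Q²Rc²/2, window Q·Rc ≤ 1.0), sequential
  two-population rod decomposition (fibrils + protofibrils), and Kratky
  shape classification (bell / plateau / rising).
* **Full-curve mixture fitting**: bounded Levenberg–Marquardt with
  seeded Latin-hypercube multi-start, curvature and bootstrap
  uncertainties, forward-intensity species fractions, and AIC-style
  model ranking (χ² + 2k).
* **Congo Red kinetics**: the I(538)/I(505) bound/free dye ratio as a
  β-structure proxy, its two-Gaussian area-vs-intensity validation, and
  replicate-averaged kinetic traces.
* **CD band-shape classification**: native-like (208/222 nm minima) vs
  β-rich (single ~215 nm minimum), scale-invariant.
* **Sigmoidal kinetics**: 4-parameter logistic fits with
  tangent-intercept lag, censoring for unfinished/flat traces, and
  condition comparison with a "blocked" call.
* **Seeded synthetic generators** for every studied solvent condition,
  standing in for the (undeposited) beamline and spectrometer data.

## Worked example

The signature end-state analysis: a fibrillated lysozyme solution
contains two rod families. Their cross sections come out model-free:

```r
library(fibrilr)

q <- seq(0.002, 0.06, length.out = 200)
mix <- species_mixture(
  cylinder_species(radius = 108.9, length = 4000, scale = 1),  # fibrils
  cylinder_species(radius = 42.4,  length = 4000, scale = 1))  # protofibrils
two_population_rod_fit(mixture_intensity(q, mix))
#> Two-population rod-like Guinier decomposition
#>   large population: Rc = 72.37 A (window [0.004623, 0.01366])
#>   small population: Rc = 28.47 A (window [0.03464, 0.0463])
```

The two families resolve to their mature-fibril (Rc = 108.9/√2 ≈ 77 Å)
and protofibril (42.4/√2 ≈ 30 Å) cross sections within 10% — the
mutual contamination of the two Guinier windows sets that accuracy. A full-curve mixture
fit then quantifies the composition of an insulin end state from a
simulated measurement:

```r
true_mix <- saxs_endstate_mixtures()$insulin_final   # cylinders 38 A, 30% pd
crv <- simulate_saxs(true_mix, seq(0.008, 0.22, length.out = 70),
                     noise = 0.02, seed = 1)
spec <- fit_spec(
  species_mixture(cylinder_species(45, 2000, 0.15, scale = 0.5),
                  wormlike_species(600, 60, cross_radius = 20, scale = 0.3),
                  background = 0.002),
  free = list(
    "species1.radius"         = c(init = 45,   lower = 10, upper = 90),
    "species1.polydispersity" = c(init = 0.15, lower = 0,  upper = 0.6),
    "species1.scale"          = c(init = 0.5,  lower = 0,  upper = 10),
    "species2.scale"          = c(init = 0.3,  lower = 0,  upper = 10),
    "background"              = c(init = 0.002, lower = 0, upper = 0.1)),
  seed = 1)
fit_mixture(crv, spec, n_starts = 4)
#> Mixture fit: 2 species, chi2_red = 0.8969 (Relative error in the sum of
#> squares is at most `ftol'., 5 iterations)
#>   species1.radius          38.058 +/- 1.21
#>   species1.polydispersity  0.29599 +/- 0.0256
#>   species1.scale           0.90043 +/- 0.00922
#>   species2.scale           0.099792 +/- 0.00144
#>   background               0.0010082 +/- 8.82e-06
#>   forward-intensity fractions: 90.0%, 10.0%
```

The generating values (radius 38 Å, 30% polydispersity, 90% fibril
share) are recovered within their uncertainties. On the spectroscopy
side:

```r
ratio <- beta_ratio(simulate_cr_spectrum(bound_fraction = 0.5))
round(as.numeric(ratio), 3)
#> [1] 1.03
classify_state(simulate_cd_spectrum(c(beta = 1)))$label
#> [1] "beta_rich"
```

See `vignettes/fibrilr-methods.Rmd` for the models, parameter
conventions, numerical choices and limitations.

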