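# Seeded parameter-recovery machinery shared by the acceptance checks:
# simulate a noisy end-state curve from a known mixture, rebuild a fitting
# template whose initial values do not use the truth (the cylinder radius
# is initialised from a rod-like Guinier pre-analysis, the standard
# practice on real curves), fit, and collect the estimates.

recovery_q_grid <- seq(0.008, 0.22, length.out = 70)

# One replicate of the cylinder + disordered-chain scenarios
# (lysozyme / insulin end states). The fit is staged, as on real curves:
# radius and scales first with the polydispersity held at a nominal 0.25
# (radius and spread trade off strongly, and releasing both at once can
# park the optimizer at the spread bound), then everything released from
# the stage-one solution.
recover_cylinder_once <- function(true_mix, seed, noise = 0.02,
                                  n_starts = 2L) {
  crv <- simulate_saxs(true_mix, recovery_q_grid, noise = noise,
                       seed = seed)
  r_init <- tryCatch(
    min(max(sqrt(2) * rodlike_guinier_fit(crv)$size, 18), 80),
    error = function(e) 45)
  chain <- true_mix$species[[2L]]
  tmpl <- species_mixture(
    cylinder_species(r_init, true_mix$species[[1L]]$length,
                     polydispersity = 0.25, scale = 0.5),
    wormlike_species(chain$contour_length, chain$kuhn_length,
                     chain$cross_radius, scale = 0.3),
    background = 0.002)
  stage1 <- fit_mixture(crv, fit_spec(tmpl, free = list(
    "species1.radius" = c(init = r_init, lower = 10, upper = 90),
    "species1.scale" = c(init = 0.5, lower = 0, upper = 10),
    "species2.scale" = c(init = 0.3, lower = 0, upper = 10),
    "background" = c(init = 0.002, lower = 0, upper = 0.1)),
    seed = seed), n_starts = n_starts)
  p1 <- coef(stage1)
  sp2 <- fit_spec(tmpl, free = list(
    "species1.radius" = c(init = unname(p1["species1.radius"]),
                          lower = 10, upper = 90),
    "species1.polydispersity" = c(init = 0.25, lower = 0, upper = 0.6),
    "species1.scale" = c(init = unname(p1["species1.scale"]),
                         lower = 0, upper = 10),
    "species2.scale" = c(init = unname(p1["species2.scale"]),
                         lower = 0, upper = 10),
    "background" = c(init = unname(p1["background"]),
                     lower = 0, upper = 0.1)),
    seed = seed)
  fit <- fit_mixture(crv, sp2, n_starts = 1L)
  c(radius = unname(coef(fit)["species1.radius"]),
    polydispersity = unname(coef(fit)["species1.polydispersity"]),
    fraction = fit$species_fractions[1L])
}

# One replicate of the two worm-like-chain scenario (lysozyme + trehalose
# end state); contour and Kuhn lengths are held at their template values,
# the cross radii and scales are free.
recover_wormlike_once <- function(true_mix, seed, noise = 0.02,
                                  n_starts = 2L) {
  crv <- simulate_saxs(true_mix, recovery_q_grid, noise = noise,
                       seed = seed)
  s1 <- true_mix$species[[1L]]
  s2 <- true_mix$species[[2L]]
  tmpl <- species_mixture(
    wormlike_species(s1$contour_length, s1$kuhn_length, 12, scale = 0.4),
    wormlike_species(s2$contour_length, s2$kuhn_length, 12, scale = 0.4),
    background = 0.002)
  sp <- fit_spec(tmpl, free = list(
    "species1.cross_radius" = c(init = 12, lower = 2, upper = 40),
    "species2.cross_radius" = c(init = 12, lower = 2, upper = 40),
    "species1.scale" = c(init = 0.4, lower = 0, upper = 10),
    "species2.scale" = c(init = 0.4, lower = 0, upper = 10),
    "background" = c(init = 0.002, lower = 0, upper = 0.1)),
    seed = seed)
  fit <- fit_mixture(crv, sp, n_starts = n_starts)
  c(rc1 = unname(coef(fit)["species1.cross_radius"]),
    rc2 = unname(coef(fit)["species2.cross_radius"]))
}
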