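# Seeded generators that emulate the beamline and spectrometer observables:
# SAXS curves with counting-statistics noise, Congo Red two-band spectra
# whose bound fraction follows a sigmoidal fibrillation time course, CD
# spectra as combinations of secondary-structure basis bands, and named
# end-state fixtures for every studied solvent condition. Every generator
# is a pure function of (configuration, seed).

#' Simulate a SAXS measurement of a mixture
#'
#' Evaluates the mixture model intensity and adds Gaussian noise with the
#' counting-statistics shape \eqn{\sigma_i = noise \sqrt{I_i \Delta Q_i}}
#' (\eqn{\Delta Q_i} the local bin width). The `sigma` column of the
#' returned curve carries the exact noise model used. `noise = 0` returns
#' the exact model curve (without a `sigma` column).
#'
#' @param mixture A [species_mixture()].
#' @param q_grid Momentum transfer grid, \eqn{\mathrm{\AA}^{-1}}.
#' @param noise Counting-noise scale (dimensionless); 0.02 gives roughly
#'   0.2-3% relative error over a typical protein curve.
#' @param seed Integer seed; the same seed reproduces the curve exactly.
#' @param label Curve label.
#' @return A [saxs_curve()].
#' @examples
#' mix <- species_mixture(cylinder_species(40, 2000, scale = 1))
#' crv <- simulate_saxs(mix, seq(0.01, 0.2, length.out = 50), 0.02, seed = 1)
#' @export
simulate_saxs <- function(mixture, q_grid, noise = 0.02, seed = 1L,
                          label = "synthetic") {
  model <- mixture_intensity(q_grid, mixture, label = label)
  if (noise == 0) return(model)
  dq <- diff(q_grid)
  dq <- c(dq[1L], dq)
  sigma <- noise * sqrt(pmax(model$intensity, 0) * dq)
  sigma <- pmax(sigma, 1e-12 * max(model$intensity))
  set.seed(seed)
  saxs_curve(q_grid, model$intensity + stats::rnorm(length(q_grid), 0, sigma),
             sigma = sigma, label = label)
}

#' Solvent-condition configuration
#'
#' One studied condition: protein, trehalose and NaCl content, plus the
#' time grid, seed and noise scale used by the generators. Only the
#' combinations actually studied are accepted (lysozyme: 0/150/300 mM
#' trehalose crossed with 0/25/50 mM NaCl; insulin: 0/300 mM trehalose
#' crossed with 0/100 mM NaCl).
#'
#' @param protein `"lysozyme"` or `"insulin"`.
#' @param trehalose_mM Trehalose concentration, mM.
#' @param nacl_mM NaCl concentration, mM.
#' @param time_grid Sampling times, minutes; default: every 15 min over
#'   the condition's experiment span.
#' @param seed Integer seed (mandatory).
#' @param noise Counting-noise scale for derived spectra.
#' @return An object of class `"scenario_config"` carrying the kinetic
#'   parameters of the condition from the shipped scenario table.
#' @examples
#' scenario_config("lysozyme", 150, 0, seed = 7)
#' @export
scenario_config <- function(protein, trehalose_mM, nacl_mM,
                            time_grid = NULL, seed, noise = 0.005) {
  if (missing(seed)) stop("'seed' is mandatory for a scenario")
  tab <- scenario_table()
  row <- tab[tab$protein == protein & tab$trehalose_mM == trehalose_mM &
               tab$nacl_mM == nacl_mM, ]
  if (nrow(row) != 1L)
    stop("unknown condition: ", protein, " / trehalose ", trehalose_mM,
         " mM / NaCl ", nacl_mM, " mM. Valid conditions:\n  ",
         paste(sprintf("%s treh=%g NaCl=%g", tab$protein, tab$trehalose_mM,
                       tab$nacl_mM), collapse = "\n  "))
  if (is.null(time_grid)) time_grid <- seq(0, row$t_max_min, by = 15)
  structure(list(protein = protein, trehalose_mM = trehalose_mM,
                 nacl_mM = nacl_mM, time_grid = time_grid,
                 seed = as.integer(seed), noise = noise,
                 params = as.list(row)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario: %s, trehalose %g mM, NaCl %g mM (seed %d)\n",
              x$protein, x$trehalose_mM, x$nacl_mM, x$seed))
  cat(sprintf("  t1/2 = %g min, rate = %g /min, plateau fraction = %g\n",
              x$params$t_half_min, x$params$rate_per_min,
              x$params$plateau_frac))
  invisible(x)
}

#' Condition parameter table
#'
#' Reads the shipped per-condition kinetic parameter table (a plain CSV
#' under `extdata`, so the encoded orderings are auditable): logistic
#' midpoint, rate and plateau bound-fraction for every studied
#' protein/trehalose/NaCl combination.
#'
#' @return A data frame.
#' @export
scenario_table <- function() {
  path <- system.file("extdata", "scenario_table.csv", package = "fibrilr",
                      mustWork = TRUE)
  utils::read.csv(path, comment.char = "#")
}

#' Bound-CR fraction versus time for a condition
#'
#' Logistic fibrillation trajectory
#' \eqn{f(t) = plateau / (1 + e^{-k(t - t_{1/2})})} with the condition's
#' tabulated parameters; always within `[0, 1]`.
#'
#' @param config A [scenario_config()].
#' @return Numeric vector of bound fractions over `config$time_grid`.
#' @export
fibrillation_timecourse <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  p <- config$params
  f <- p$plateau_frac /
    (1 + exp(-p$rate_per_min * (config$time_grid - p$t_half_min)))
  pmin(1, pmax(0, f))
}

# Congo Red band defaults: free dye ~505 nm, bound dye ~540 nm, both with
# 50 nm FWHM. Equal widths make the band-area ratio coincide with the
# band-amplitude ratio - the equivalence verified experimentally in the
# preparatory phase of the study - while the strong overlap still
# reproduces the broad composite signal of partially fibrillated samples.
.cr_bands <- list(free = list(center = 505, sd = 50 / 2.3548),
                  bound = list(center = 540, sd = 50 / 2.3548))

#' Simulate a Congo Red absorbance spectrum
#'
#' Two overlapping Gaussian bands: the free-dye band (centre ~505 nm)
#' weighted by \eqn{1 - f} and the bound-dye band (centre ~540 nm)
#' weighted by \eqn{f}, plus seeded Gaussian noise. The resulting
#' [beta_ratio()] is strictly increasing in the bound fraction `f`.
#'
#' @param bound_fraction Bound-CR fraction \eqn{f \in [0, 1]}.
#' @param wavelength Wavelength grid, nm.
#' @param noise Additive noise sd, AU.
#' @param seed Integer seed.
#' @param amplitude Total band amplitude, AU.
#' @param time_label,replicate Metadata passed to the spectrum.
#' @return An [absorbance_spectrum()].
#' @export
simulate_cr_spectrum <- function(bound_fraction, wavelength = 400:650,
                                 noise = 0, seed = 1L, amplitude = 1,
                                 time_label = NULL, replicate = NULL) {
  if (bound_fraction < 0 || bound_fraction > 1)
    stop("'bound_fraction' must lie in [0, 1]")
  ab <- amplitude * (
    (1 - bound_fraction) *
      gaussian_band(wavelength, 1, .cr_bands$free$center, .cr_bands$free$sd) +
    bound_fraction *
      gaussian_band(wavelength, 1, .cr_bands$bound$center, .cr_bands$bound$sd))
  if (noise > 0) {
    set.seed(seed)
    ab <- ab + stats::rnorm(length(wavelength), 0, noise)
  }
  absorbance_spectrum(wavelength, ab, time_label = time_label,
                      replicate = replicate)
}

#' Simulate a replicated Congo Red kinetic experiment
#'
#' Generates `n_replicates` noisy CR spectra at every time point of the
#' condition's trajectory and assembles them into a [kinetic_trace()] with
#' per-time mean and standard error - the same averaging applied to the
#' real measurements (at least nine replicas per condition).
#'
#' @param config A [scenario_config()].
#' @param n_replicates Spectra per time point (default 9).
#' @return A [kinetic_trace()].
#' @export
simulate_cr_kinetics <- function(config, n_replicates = 9L) {
  stopifnot(inherits(config, "scenario_config"))
  f <- fibrillation_timecourse(config)
  spectra <- list()
  k <- 0L
  for (i in seq_along(config$time_grid)) {
    for (r in seq_len(n_replicates)) {
      k <- k + 1L
      spectra[[k]] <- simulate_cr_spectrum(
        f[i], noise = config$noise,
        seed = config$seed + 1000L * i + r,
        time_label = config$time_grid[i], replicate = r)
    }
  }
  build_kinetic_trace(spectra,
                      label = sprintf("%s_treh%g_nacl%g", config$protein,
                                      config$trehalose_mM, config$nacl_mM))
}

# CD basis band shapes (Gaussian, mdeg): canonical alpha+beta native
# signature (minima 208/222 nm, positive lobe below 200), beta-sheet
# (single 215 nm minimum, positive ~198) and disordered coil (single
# ~198 nm minimum).
cd_basis_signal <- function(wavelength, native = 0, beta = 0, coil = 0) {
  g <- function(a, c0, s) gaussian_band(wavelength, a, c0, s)
  native * (g(-10, 208, 5) + g(-9.5, 222, 5.5) + g(12, 193, 5)) +
    beta * (g(-11, 215, 8) + g(7, 197, 5)) +
    coil * (g(-12, 198, 7) + g(1.5, 220, 12))
}

#' Simulate a far-UV CD spectrum
#'
#' Linear combination of Gaussian basis bands reproducing the canonical
#' secondary-structure signatures (native alpha+beta: minima at 208 and
#' 222 nm; beta-sheet: single minimum at ~215 nm; coil: single minimum at
#' ~198 nm), plus seeded noise. All-zero fractions give a flat spectrum.
#'
#' @param fractions Named numeric vector/list with any of `native`,
#'   `beta`, `coil`; each non-negative, sum at most 1.
#' @param wavelength Wavelength grid, nm (default 190-260).
#' @param noise Additive noise sd, mdeg.
#' @param seed Integer seed.
#' @return A [cd_spectrum()].
#' @examples
#' classify_state(simulate_cd_spectrum(c(native = 1)))$label
#' @export
simulate_cd_spectrum <- function(fractions, wavelength = 190:260,
                                 noise = 0, seed = 1L) {
  f <- c(native = 0, beta = 0, coil = 0)
  fractions <- unlist(fractions)
  bad <- setdiff(names(fractions), names(f))
  if (length(bad)) stop("unknown state fraction(s): ",
                        paste(bad, collapse = ", "))
  f[names(fractions)] <- fractions
  if (any(f < 0) || sum(f) > 1 + 1e-9)
    stop("state fractions must be non-negative and sum to at most 1")
  sig <- cd_basis_signal(wavelength, f[["native"]], f[["beta"]], f[["coil"]])
  if (noise > 0) {
    set.seed(seed)
    sig <- sig + stats::rnorm(length(wavelength), 0, noise)
  }
  cd_spectrum(wavelength, sig)
}

#' The named SAXS end-state scenarios
#'
#' The six generating mixtures behind the SAXS fixtures: native lysozyme
#' with and without trehalose (the hen egg-white lysozyme crystal
#' structure shipped with bio3d, PDB 1HEL, with the default hydration
#' shell; trehalose only changes the solvent contrast, i.e. the scale),
#' fibrillated lysozyme (polydisperse 40 A cylinders plus disordered
#' chains), the lysozyme + trehalose final state (two worm-like-chain
#' species with cross radii 9.5 and 15.8 A), fibrillated insulin (38 A
#' cylinders at 30% polydispersity plus minor 20 A-cross-radius chains)
#' and the insulin + trehalose final state (85% disordered). Cylinder
#' lengths are nominal (L = 2000 A, far beyond the probed 1/Q range):
#' only cross-sectional quantities are meaningful.
#'
#' @return Named list of [species_mixture()] objects.
#' @examples
#' names(saxs_endstate_mixtures())
#' @export
saxs_endstate_mixtures <- function() {
  lyz_pdb <- system.file("examples", "1hel.pdb", package = "bio3d")
  lyz <- function(scale) read_pdb_structure(lyz_pdb, scale = scale)
  list(
    lysozyme_native = species_mixture(
      lyz(0.02), background = 5e-4),
    lysozyme_native_trehalose = species_mixture(
      lyz(0.014), background = 5e-4),
    lysozyme_final = species_mixture(
      cylinder_species(40, 2000, polydispersity = 0.2, scale = 0.8),
      wormlike_species(350, 35, cross_radius = 15, aggregation_number = 5,
                       scale = 0.2),
      background = 1e-3),
    lysozyme_trehalose_final = species_mixture(
      wormlike_species(250, 50, cross_radius = 9.5, aggregation_number = 3,
                       scale = 0.5),
      wormlike_species(700, 60, cross_radius = 15.8, aggregation_number = 10,
                       scale = 0.5),
      background = 1e-3),
    insulin_final = species_mixture(
      cylinder_species(38, 2000, polydispersity = 0.30, scale = 0.9),
      wormlike_species(600, 60, cross_radius = 20, aggregation_number = 8,
                       scale = 0.1),
      background = 1e-3),
    insulin_trehalose_final = species_mixture(
      cylinder_species(60, 2000, polydispersity = 0.30, scale = 0.15),
      wormlike_species(600, 60, cross_radius = 20, aggregation_number = 8,
                       scale = 0.85),
      background = 1e-3)
  )
}

mixture_manifest <- function(mix) {
  list(background = mix$background,
       species = lapply(mix$species, function(s) {
         if (inherits(s, "atomic_structure"))
           c(list(type = "atomic", n_atoms = nrow(s$atoms)),
             s[c("shell_contrast", "shell_thickness", "scale")])
         else c(list(type = species_type(s)),
                s[setdiff(names(s), "distribution")])
       }))
}

#' Generate the named end-state and kinetic fixtures
#'
#' Writes, under one output directory: the six SAXS end-state scenarios
#' (native lysozyme with/without trehalose, fibrillated lysozyme,
#' lysozyme + trehalose disordered final state, fibrillated insulin,
#' insulin + trehalose) as 3-column `.dat` files with counting noise; a
#' Congo Red kinetic-trace CSV for every studied solvent condition; and a
#' `manifest.json` recording the generating parameters of every file.
#' Bit-identical for identical seeds.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer master seed; per-file seeds are derived from it.
#' @param q_grid Q grid for the SAXS fixtures.
#' @param noise Counting-noise scale for the SAXS fixtures.
#' @param n_replicates CR replicates per time point.
#' @return Invisibly, the manifest list.
#' @export
generate_fixtures <- function(dir, seed = 1L,
                              q_grid = seq(0.008, 0.25, length.out = 100),
                              noise = 0.02, n_replicates = 9L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, noise = noise,
                   q_grid = list(min = min(q_grid), max = max(q_grid),
                                 n = length(q_grid)),
                   saxs = list(), kinetics = list())
  mixes <- saxs_endstate_mixtures()
  for (i in seq_along(mixes)) {
    name <- names(mixes)[i]
    crv <- simulate_saxs(mixes[[i]], q_grid, noise = noise,
                         seed = seed + i, label = name)
    f <- file.path(dir, paste0(name, ".dat"))
    write_saxs_dat(crv, f)
    manifest$saxs[[name]] <- c(list(file = basename(f), seed = seed + i),
                               mixture_manifest(mixes[[i]]))
  }
  tab <- scenario_table()
  for (i in seq_len(nrow(tab))) {
    cfg <- scenario_config(tab$protein[i], tab$trehalose_mM[i],
                           tab$nacl_mM[i], seed = seed + 100L * i)
    tr <- simulate_cr_kinetics(cfg, n_replicates = n_replicates)
    f <- file.path(dir, paste0(tr$label, ".csv"))
    write_kinetic_trace_csv(tr, f)
    manifest$kinetics[[tr$label]] <-
      list(file = basename(f), seed = cfg$seed,
           n_replicates = n_replicates, params = cfg$params)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
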