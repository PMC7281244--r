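#' Scatterer populations
#'
#' Constructors for the particle species whose form factors the package
#' computes: rigid cylinders with optional radius polydispersity (mature
#' amyloid fibrils), Pedersen-Schurtenberger worm-like chains (disordered /
#' unfolded protein), uniform spheres, and explicit atomic structures.
#' Every species carries a `scale` in \eqn{cm^{-1}}: its forward intensity
#' \eqn{d\Sigma/d\Omega(0)}, i.e. number density times squared contrast
#' times squared volume absorbed into one parameter.
#'
#' @param radius Mean geometric cross-section radius R, \eqn{\mathrm{\AA}}.
#' @param length Cylinder length L, \eqn{\mathrm{\AA}}.
#' @param polydispersity Relative standard deviation of the radius
#'   distribution, in `[0, 0.6]`. `0` means monodisperse.
#' @param scale Forward-intensity weight, \eqn{cm^{-1}}, non-negative.
#' @param distribution Radius distribution for polydisperse cylinders:
#'   `"gaussian"` (default; truncated at R > 0) or `"schulz"`.
#' @return An object of class `c("<type>_species", "saxs_species")`.
#' @name species
#' @examples
#' cylinder_species(radius = 40, length = 2000, polydispersity = 0.2)
#' wormlike_species(contour_length = 400, kuhn_length = 40, cross_radius = 9.5)
NULL

#' @rdname species
#' @export
cylinder_species <- function(radius, length, polydispersity = 0, scale = 1,
                             distribution = c("gaussian", "schulz")) {
  distribution <- match.arg(distribution)
  stopifnot(is.numeric(radius), is.numeric(length))
  if (radius <= 0) stop("'radius' must be positive")
  if (length <= 0) stop("'length' must be positive")
  if (polydispersity < 0 || polydispersity > 0.6)
    stop("'polydispersity' must lie in [0, 0.6]")
  if (scale < 0) stop("'scale' must be non-negative")
  structure(list(radius = radius, length = length,
                 polydispersity = polydispersity, scale = scale,
                 distribution = distribution),
            class = c("cylinder_species", "saxs_species"))
}

#' @rdname species
#' @param contour_length Worm-like chain contour length L, \eqn{\mathrm{\AA}}.
#' @param kuhn_length Kuhn (statistical segment) length b, \eqn{\mathrm{\AA}};
#'   must not exceed the contour length.
#' @param cross_radius Geometric radius of the circular cross section,
#'   \eqn{\mathrm{\AA}} (0 for an infinitely thin chain). The corresponding
#'   cross-section radius of gyration is `cross_radius / sqrt(2)`; both
#'   conventions are reported by `summary()`.
#' @param aggregation_number Monomers per chain (metadata, >= 1; not a fit
#'   constraint).
#' @export
wormlike_species <- function(contour_length, kuhn_length, cross_radius = 0,
                             aggregation_number = 1, scale = 1) {
  if (!is.numeric(kuhn_length) || kuhn_length <= 0)
    stop("'kuhn_length' must be positive")
  if (contour_length < kuhn_length)
    stop("'contour_length' must be >= 'kuhn_length'")
  if (cross_radius < 0) stop("'cross_radius' must be non-negative")
  if (aggregation_number < 1) stop("'aggregation_number' must be >= 1")
  if (scale < 0) stop("'scale' must be non-negative")
  structure(list(contour_length = contour_length, kuhn_length = kuhn_length,
                 cross_radius = cross_radius,
                 aggregation_number = aggregation_number, scale = scale),
            class = c("wormlike_species", "saxs_species"))
}

#' @rdname species
#' @export
sphere_species <- function(radius, scale = 1) {
  if (!is.numeric(radius) || radius <= 0) stop("'radius' must be positive")
  if (scale < 0) stop("'scale' must be non-negative")
  structure(list(radius = radius, scale = scale),
            class = c("sphere_species", "saxs_species"))
}

#' Atomic structure for Debye-formula scattering
#'
#' Holds heavy-atom coordinates plus hydration-shell settings. Use
#' [read_pdb_structure()] to build one from a PDB file; hydrogens, when
#' absent from the model (the usual case for X-ray structures), are merged
#' into the heavy-atom scattering factors.
#'
#' @param atoms Data frame with columns `element` (symbol), `x`, `y`, `z`
#'   (\eqn{\mathrm{\AA}}) and optionally `occupancy` (default 1).
#' @param shell_contrast Excess electron density of the hydration shell over
#'   bulk water, \eqn{e^-/\mathrm{\AA}^3}; default 0.03.
#' @param shell_thickness Shell thickness, \eqn{\mathrm{\AA}}; default 3.
#' @param scale Forward-intensity weight, \eqn{cm^{-1}}.
#' @return An object of class `c("atomic_structure", "saxs_species")`.
#' @export
atomic_structure <- function(atoms, shell_contrast = 0.03,
                             shell_thickness = 3, scale = 1) {
  stopifnot(is.data.frame(atoms))
  need <- c("element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("'atoms' needs columns: ", paste(need, collapse = ", "))
  if (nrow(atoms) < 1L) stop("'atoms' must contain at least one atom")
  if (!all(is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (shell_thickness < 0) stop("'shell_thickness' must be non-negative")
  if (scale < 0) stop("'scale' must be non-negative")
  structure(list(atoms = atoms, shell_contrast = shell_contrast,
                 shell_thickness = shell_thickness, scale = scale),
            class = c("atomic_structure", "saxs_species"))
}

#' Read an atomic structure from a PDB file
#'
#' Parses ATOM/HETATM records via [bio3d::read.pdb()], keeping alternate
#' location 'A' (or blank) and carrying occupancies. Water molecules are
#' dropped; the bound solvent is represented instead by the hydration-shell
#' model of [debye_intensity_from_structure()].
#'
#' @param path Path to a PDB file.
#' @param keep_hetatm Keep non-water HETATM records? Default `FALSE`.
#' @inheritParams atomic_structure
#' @return An [atomic_structure()].
#' @examples
#' lyz <- read_pdb_structure(system.file("examples", "1hel.pdb",
#'                                       package = "bio3d"))
#' nrow(lyz$atoms)
#' @export
read_pdb_structure <- function(path, keep_hetatm = FALSE,
                               shell_contrast = 0.03, shell_thickness = 3,
                               scale = 1) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$alt %in% c("", "A", NA), , drop = FALSE]
  a <- a[a$resid != "HOH", , drop = FALSE]
  if (!keep_hetatm) a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("no usable ATOM records in ", path)
  elem <- toupper(trimws(a$elesy))
  miss <- !nzchar(elem) | is.na(elem)
  if (any(miss)) elem[miss] <- toupper(substr(trimws(a$elety[miss]), 1L, 1L))
  occ <- a$o
  occ[is.na(occ)] <- 1
  atomic_structure(
    data.frame(element = elem, x = a$x, y = a$y, z = a$z, occupancy = occ),
    shell_contrast = shell_contrast, shell_thickness = shell_thickness,
    scale = scale
  )
}

#' Mixture of scatterer species
#'
#' Dilute-limit mixture: total intensity is the sum of the per-species
#' contributions plus a flat background (no interparticle interference
#' terms).
#'
#' @param ... [saxs_species] objects (or a single list of them).
#' @param background Flat additive term, \eqn{cm^{-1}}, non-negative.
#' @return An object of class `"species_mixture"`.
#' @examples
#' mix <- species_mixture(cylinder_species(40, 2000),
#'                        wormlike_species(300, 30, 9.5), background = 1e-3)
#' mix
#' @export
species_mixture <- function(..., background = 0) {
  species <- list(...)
  if (length(species) == 1L && !inherits(species[[1L]], "saxs_species") &&
      is.list(species[[1L]]))
    species <- species[[1L]]
  if (length(species) == 0L) stop("a mixture needs at least one species")
  ok <- vapply(species, inherits, logical(1L), what = "saxs_species")
  if (!all(ok)) stop("all components must be saxs_species objects")
  if (background < 0) stop("'background' must be non-negative")
  structure(list(species = species, background = background),
            class = "species_mixture")
}

species_type <- function(s) sub("_species$", "", class(s)[1L])

#' @export
print.species_mixture <- function(x, ...) {
  cat(sprintf("Species mixture (%d species, background %.3g cm^-1)\n",
              length(x$species), x$background))
  for (i in seq_along(x$species)) {
    s <- x$species[[i]]
    cat(sprintf("  [%d] %s: %s\n", i,
                if (inherits(s, "atomic_structure")) "atomic"
                else species_type(s),
                paste(vapply(
                  setdiff(names(s), c("atoms", "distribution")),
                  function(n) sprintf("%s=%.4g", n, as.numeric(s[[n]])[1L]),
                  character(1L)), collapse = ", ")))
  }
  invisible(x)
}
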