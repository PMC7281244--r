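# Form factors and absolute-scale intensities for all species types.
# Conventions, package-wide: Q in A^-1, lengths in A, intensities in cm^-1.
# Every normalized form factor satisfies P(0) = 1; species contributions are
# scale * <P(Q)> so that the forward intensity equals `scale`.

.ff_cache <- new.env(parent = emptyenv())

gl_nodes <- function(n, a = 0, b = 1) {
  key <- sprintf("gl_%d_%.17g_%.17g", n, a, b)
  if (!is.null(.ff_cache[[key]])) return(.ff_cache[[key]])
  g <- pracma::gaussLegendre(n, a, b)
  .ff_cache[[key]] <- g
  g
}

sinc <- function(x) ifelse(abs(x) < 1e-8, 1 - x^2 / 6, sin(x) / x)

# 2 J1(x) / x, the amplitude of a uniform disc; series near zero.
disc_amp <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-6
  out[small] <- 1 - x[small]^2 / 8
  out[!small] <- 2 * besselJ(x[!small], 1) / x[!small]
  out
}

# Tabulated disc amplitude on a 0.005-spaced grid with linear interpolation
# (|error| < 5e-6, well inside the 1e-4 quadrature contract); exact besselJ
# beyond the table. Used only inside the cylinder orientation average, where
# it is the hot path.
disc_amp_fast <- function(x) {
  xmax <- max(x, 50)
  tab <- .ff_cache$disc_tab
  if (is.null(tab) || tab$xmax < xmax) {
    grid <- seq(0, xmax * 1.2, by = 0.005)
    tab <- list(xmax = xmax * 1.2, grid = grid, val = disc_amp(grid))
    .ff_cache$disc_tab <- tab
  }
  out <- numeric(length(x))
  inside <- x <= tab$xmax
  out[inside] <- approx(tab$grid, tab$val, x[inside])$y
  if (any(!inside)) out[!inside] <- disc_amp(x[!inside])
  out
}

#' Sphere form factor
#'
#' Normalized form factor of a uniform sphere,
#' \eqn{P(Q) = [3(\sin x - x\cos x)/x^3]^2} with \eqn{x = QR}. Its Guinier
#' radius is \eqn{R_g = \sqrt{3/5}\,R}; the first intensity zero sits at
#' \eqn{QR \approx 4.4934} (smallest positive root of \eqn{\tan x = x}).
#'
#' @param q Momentum transfer grid, \eqn{\mathrm{\AA}^{-1}}.
#' @param radius Sphere radius, \eqn{\mathrm{\AA}}, positive.
#' @return Normalized intensity, `P(0) = 1`, in `[0, 1]`.
#' @examples
#' sphere_form_factor(c(1e-6, 0.05), radius = 20.66)
#' @export
sphere_form_factor <- function(q, radius) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("'radius' must be a single positive number")
  x <- q * radius
  amp <- ifelse(abs(x) < 1e-4,
                1 - x^2 / 10,
                3 * (sin(x) - x * cos(x)) / x^3)
  amp^2
}

# Orientation-averaged form factor of a monodisperse cylinder:
# Gauss-Legendre quadrature over u = cos(angle between Q and the axis),
# u in [0, 1], under the cubic substitution u = t^3 that concentrates nodes
# in the sharp sinc^2 peak near u = 0 of long cylinders. The node count
# doubles from `n0` until the peak-normalized change is below `tol`.
cylinder_orient_avg <- function(q, radius, length, n0 = 64L, tol = 1e-4,
                                max_n = 4096L) {
  eval_n <- function(n) {
    g <- gl_nodes(n, 0, 1)
    u <- g$x^3
    w <- g$w * 3 * g$x^2
    s <- sqrt(pmax(0, 1 - u^2))
    amp <- disc_amp_fast(outer(q, s * radius)) *
      sinc(outer(q, u * length / 2))
    drop((amp^2) %*% w)
  }
  n <- as.integer(n0)
  p <- eval_n(n)
  repeat {
    n2 <- 2L * n
    p2 <- eval_n(n2)
    err <- max(abs(p2 - p)) / max(p2)
    if (err < tol) return(p2)
    if (n2 >= max_n)
      stop(sprintf(paste0("cylinder orientation quadrature did not converge",
                          " (n = %d, peak-normalized change %.3g > %.3g)"),
                   n2, err, tol))
    n <- n2
    p <- p2
  }
}

# Orientation workspace for a fixed (q grid, length, node count): the mapped
# abscissae, the q x nodes matrices of q*sin(alpha) and of the longitudinal
# sinc factor, and the quadrature weights. These depend on everything except
# the radius, so they are cached (keyed by length/n and verified with
# identical() on the q grid) and reused across radius nodes and optimizer
# iterations.
orient_workspace <- function(q, length, n) {
  key <- sprintf("ws_%g_%d_%d", length, n, base::length(q))
  ws <- .ff_cache[[key]]
  if (!is.null(ws) && identical(ws$q, q)) return(ws)
  g <- gl_nodes(n, 0, 1)
  u <- g$x^3
  w <- g$w * 3 * g$x^2
  s <- sqrt(pmax(0, 1 - u^2))
  ws <- list(q = q, qs = outer(q, s), sc = sinc(outer(q, u * length / 2)),
             w = w)
  .ff_cache[[key]] <- ws
  ws
}

# Radius-averaged orientation integral at one node count, reusing the
# workspace; `radii`/`rw` may be a single radius with weight 1.
cyl_avg_at_n <- function(q, radii, rw, length, n) {
  ws <- orient_workspace(q, length, n)
  p <- numeric(base::length(q))
  for (j in seq_along(radii)) {
    amp <- disc_amp_fast(ws$qs * radii[j]) * ws$sc
    p <- p + rw[j] * drop((amp * amp) %*% ws$w)
  }
  p
}

# Adaptive version of the above: node count doubles until the
# peak-normalized change of the averaged curve is below tol.
cyl_avg_adaptive <- function(q, radii, rw, length, n0 = 64L, tol = 1e-4,
                             max_n = 4096L) {
  n <- as.integer(n0)
  p <- cyl_avg_at_n(q, radii, rw, length, n)
  repeat {
    n2 <- 2L * n
    p2 <- cyl_avg_at_n(q, radii, rw, length, n2)
    err <- max(abs(p2 - p)) / max(p2)
    if (err < tol) return(list(p = p2, n = n2))
    if (n2 >= max_n)
      stop(sprintf(paste0("cylinder orientation quadrature did not converge",
                          " (n = %d, peak-normalized change %.3g > %.3g)"),
                   n2, err, tol))
    n <- n2
    p <- p2
  }
}

# Nodes and weights of the radius distribution for a polydisperse cylinder.
# Gaussian: truncated at R > 0 and at +/- 3 standard deviations, on a fixed
# Gauss-Legendre grid, renormalized. Schulz: same grid over the equivalent
# +/- 3 sd range. Weights carry the R^4 volume-squared factor so that the
# population average is intensity-weighted and I(0) still equals `scale`.
radius_quadrature <- function(radius, polydispersity,
                              distribution = "gaussian", n = 21L) {
  sd <- radius * polydispersity
  lo <- max(radius * 1e-6, radius - 3 * sd)
  hi <- radius + 3 * sd
  g <- gl_nodes(n, lo, hi)
  dens <- switch(distribution,
    gaussian = stats::dnorm(g$x, mean = radius, sd = sd),
    schulz = {
      z <- 1 / polydispersity^2 - 1
      stats::dgamma(g$x, shape = z + 1, rate = (z + 1) / radius)
    },
    stop("unknown radius distribution: ", distribution)
  )
  w <- g$w * dens * g$x^4
  list(r = g$x, w = w / sum(w))
}

#' Cylinder intensity contribution
#'
#' Absolute-scale intensity of a population of rigid circular cylinders,
#' orientation-averaged by adaptive Gauss-Legendre quadrature and, when
#' `polydispersity > 0`, averaged over a truncated-Gaussian (or Schulz)
#' radius distribution with intensity (volume-squared) weighting. The
#' forward intensity equals `species$scale`.
#'
#' @param q Momentum transfer grid, \eqn{\mathrm{\AA}^{-1}}.
#' @param species A [cylinder_species()].
#' @param n_radius Number of radius-distribution quadrature nodes.
#' @return Intensity vector, \eqn{cm^{-1}}.
#' @examples
#' cyl <- cylinder_species(radius = 40, length = 2000, polydispersity = 0.2)
#' cylinder_intensity(c(0.01, 0.05, 0.1), cyl)
#' @export
cylinder_intensity <- function(q, species, n_radius = 21L) {
  stopifnot(inherits(species, "cylinder_species"))
  if (species$scale == 0) return(numeric(length(q)) + 0)
  if (species$polydispersity < 1e-6) {
    radii <- species$radius
    rw <- 1
  } else {
    rq <- radius_quadrature(species$radius, species$polydispersity,
                            species$distribution, n = n_radius)
    radii <- rq$r
    rw <- rq$w
  }
  # the converged node count depends on the q grid and length, only weakly
  # on the radius: remember it and skip re-verification while the radius
  # stays in the verified range (e.g. across optimizer iterations)
  key <- sprintf("nconv_%g_%d", species$length, length(q))
  memo <- .ff_cache[[key]]
  if (!is.null(memo) && identical(memo$q, q) && max(radii) <= memo$rmax) {
    p <- cyl_avg_at_n(q, radii, rw, species$length, memo$n)
  } else {
    res <- cyl_avg_adaptive(q, radii, rw, species$length)
    p <- res$p
    rmax_new <- 1.5 * max(radii)
    if (!is.null(memo) && identical(memo$q, q))
      rmax_new <- max(rmax_new, memo$rmax)
    .ff_cache[[key]] <- list(q = q, n = res$n, rmax = rmax_new)
  }
  species$scale * p
}

# Benoit-Doty radius of gyration squared of a worm-like chain with contour
# length L and Kuhn length b (n = L/b):
# Rg^2 = (L b / 6) [1 - 3/(2n) + 3/(2n^2) - 3/(4n^3) (1 - e^{-2n})]
wormlike_rg2 <- function(contour_length, kuhn_length) {
  n <- contour_length / kuhn_length
  (contour_length * kuhn_length / 6) *
    (1 - 3 / (2 * n) + 3 / (2 * n^2) - 3 / (4 * n^3) * (1 - exp(-2 * n)))
}

debye_coil <- function(x2) {
  # Debye function of x2 = (q Rg)^2
  ifelse(x2 < 1e-6, 1 - x2 / 3, 2 * (exp(-x2) - 1 + x2) / x2^2)
}

# Thin-rod asymptote including the first stiffness correction:
# S(q) ~ pi/(qL) + 2/(3 q^2 L b)
rod_asymptote <- function(q, contour_length, kuhn_length) {
  pi / (q * contour_length) +
    2 / (3 * q^2 * contour_length * kuhn_length)
}

#' Worm-like chain intensity contribution
#'
#' Pedersen-Schurtenberger-type form factor of a semiflexible chain without
#' excluded-volume interactions: the Debye coil function evaluated at the
#' Benoit-Doty radius of gyration at low Q, crossing over smoothly (tanh
#' bridge in \eqn{u = Q b}) to the stiff-rod asymptote
#' \eqn{\pi/(QL) + 2/(3Q^2Lb)} at high Q, multiplied by the form factor of
#' the circular cross section of geometric radius `cross_radius`. The
#' crossover midpoint is placed where the two branches intersect
#' (\eqn{u^* = (12 - 2/3)/\pi \approx 3.61}), which makes the bridge
#' continuous. Forward intensity equals `species$scale`.
#'
#' @param q Momentum transfer grid, \eqn{\mathrm{\AA}^{-1}}.
#' @param species A [wormlike_species()].
#' @return Intensity vector, \eqn{cm^{-1}}.
#' @examples
#' wlc <- wormlike_species(contour_length = 400, kuhn_length = 40,
#'                         cross_radius = 9.5)
#' wormlike_intensity(c(0.01, 0.1, 0.4), wlc)
#' @export
wormlike_intensity <- function(q, species) {
  stopifnot(inherits(species, "wormlike_species"))
  if (species$scale == 0) return(numeric(length(q)) + 0)
  L <- species$contour_length
  b <- species$kuhn_length
  rg2 <- wormlike_rg2(L, b)
  s_coil <- debye_coil(q^2 * rg2)
  s_rod <- rod_asymptote(q, L, b)
  u <- q * b
  w <- (1 + tanh((u - 3.61) / 0.44)) / 2
  p <- (1 - w) * s_coil + w * pmin(s_rod, 1)
  if (species$cross_radius > 0)
    p <- p * disc_amp(q * species$cross_radius)^2
  species$scale * p
}

# ---- Debye formula from atomic coordinates --------------------------------

# Per-element small-angle effective scattering factors, electrons:
# f = (Z + nH) - rho_bulk (V + nH V_H), with displaced volumes V (A^3) after
# Fraser, MacRae & Suzuki (1978), bulk water 0.334 e/A^3, and nH the average
# number of bonded hydrogens merged into each heavy atom (typical protein
# stoichiometry; X-ray structures carry no H).
.element_table <- data.frame(
  element = c("H", "C", "N", "O", "S", "P", "SE", "FE", "ZN", "MG", "CA",
              "NA", "CL", "K"),
  z       = c(1, 6, 7, 8, 16, 15, 34, 26, 30, 12, 20, 11, 17, 19),
  vol     = c(5.15, 16.44, 2.49, 9.13, 19.86, 5.73, 28.73, 7.35, 9.85,
              16.77, 31.89, 4.45, 24.84, 11.01),
  n_h     = c(0, 1.2, 0.8, 0.2, 0.1, 0, 0, 0, 0, 0, 0, 0, 0, 0)
)

.rho_bulk <- 0.334  # e-/A^3, water

element_contrast <- function(element, merge_hydrogens = TRUE) {
  idx <- match(toupper(element), .element_table$element)
  if (anyNA(idx)) {
    bad <- unique(element[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  tab <- .element_table[idx, ]
  nh <- if (merge_hydrogens) tab$n_h else 0
  (tab$z + nh * 1) - .rho_bulk * (tab$vol + nh * 5.15)
}

# van der Waals radii used for shell construction only
.vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
          H = 1.20)
vdw_radius <- function(element) {
  r <- .vdw[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# Golden-spiral points on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Hydration-shell dummy scatterers
#'
#' Places dummy scatterers on the rolling-probe (solvent-accessible)
#' surface of the structure: candidate points are generated on each atom's
#' expanded sphere of radius \eqn{r_{vdw} + probe + thickness/2}, points
#' buried inside any neighbouring expanded sphere are discarded, and the
#' survivors are thinned to one per `grid` -spaced voxel. Each kept dummy
#' carries `shell_contrast * grid^2 * thickness` excess electrons.
#'
#' @param structure An [atomic_structure()].
#' @param probe Probe radius, \eqn{\mathrm{\AA}} (default 1.4, water).
#' @param grid Surface grid spacing, \eqn{\mathrm{\AA}} (default 3).
#' @return Data frame of dummy positions with an `f` column (electrons).
#' @keywords internal
#' @export
hydration_shell_sites <- function(structure, probe = 1.4, grid = 3) {
  at <- structure$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rexp <- vdw_radius(at$element) + probe + structure$shell_thickness / 2
  pts_list <- vector("list", nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    npt <- max(16L, ceiling(4 * pi * rexp[i]^2 / grid^2) * 3L)
    p <- sphere_points(npt) * rexp[i]
    p <- sweep(p, 2L, xyz[i, ], "+")
    # keep points outside every other expanded sphere
    near <- which(rowSums(sweep(xyz, 2L, xyz[i, ])^2) <
                    (rexp[i] + max(rexp))^2)
    keep <- rep(TRUE, nrow(p))
    for (j in near) {
      if (j == i) next
      keep <- keep &
        (rowSums(sweep(p, 2L, xyz[j, ])^2) >= rexp[j]^2 * 0.999999)
    }
    pts_list[[i]] <- p[keep, , drop = FALSE]
  }
  pts <- do.call(rbind, pts_list)
  if (is.null(pts) || nrow(pts) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      f = numeric(0)))
  cell <- paste(round(pts[, 1] / grid), round(pts[, 2] / grid),
                round(pts[, 3] / grid))
  pts <- pts[!duplicated(cell), , drop = FALSE]
  f <- structure$shell_contrast * grid^2 * structure$shell_thickness
  data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3], f = f)
}

#' Debye-formula form factor of an atomic structure
#'
#' Normalized small-angle form factor from explicit coordinates:
#' \eqn{I(Q) \propto \sum_{ij} f_i f_j \,\mathrm{sinc}(Q r_{ij})}, evaluated
#' through a pair-distance histogram (bin width `bin`). Per-element
#' scattering factors are electron counts reduced by the displaced-solvent
#' term (in-vacuo minus bulk), with bonded hydrogens merged into the heavy
#' atoms; an optional hydration shell of dummy scatterers at
#' `shell_contrast` excess density is added on the rolling-probe surface
#' (see [hydration_shell_sites()]). `P(0) = 1`.
#'
#' @param q Momentum transfer grid, \eqn{\mathrm{\AA}^{-1}}.
#' @param structure An [atomic_structure()].
#' @param with_shell Include the hydration shell? Default `TRUE` when
#'   `shell_contrast > 0` and `shell_thickness > 0`.
#' @param bin Pair-distance histogram bin width, \eqn{\mathrm{\AA}}.
#' @return Normalized intensity, `P(0) = 1`.
#' @examples
#' two <- atomic_structure(data.frame(element = c("O", "O"),
#'                                    x = c(0, 10), y = 0, z = 0),
#'                         shell_thickness = 0)
#' debye_intensity_from_structure(c(0.1, 0.3), two)
#' @export
debye_intensity_from_structure <- function(q, structure,
                                           with_shell = NULL, bin = 0.5) {
  stopifnot(inherits(structure, "atomic_structure"))
  at <- structure$atoms
  f <- element_contrast(at$element) * at$occupancy
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (is.null(with_shell))
    with_shell <- structure$shell_contrast != 0 &&
      structure$shell_thickness > 0
  if (with_shell) {
    sh <- hydration_shell_sites(structure)
    if (nrow(sh)) {
      xyz <- rbind(xyz, as.matrix(sh[, c("x", "y", "z")]))
      f <- c(f, sh$f)
    }
  }
  n <- nrow(xyz)
  if (n == 1L) return(rep(1, length(q)))
  # weighted pair-distance histogram
  d <- as.vector(stats::dist(xyz))
  fw <- tcrossprod(f)
  w <- fw[upper.tri(fw)]
  idx <- pmax(1L, as.integer(ceiling(d / bin)))
  nb <- max(idx)
  hist_w <- numeric(nb)
  acc <- tapply(w, idx, sum)
  hist_w[as.integer(names(acc))] <- acc
  centers <- (seq_len(nb) - 0.5) * bin
  self <- sum(f^2)
  i0 <- self + 2 * sum(hist_w)
  vapply(q, function(qq) {
    (self + 2 * sum(hist_w * sinc(qq * centers))) / i0
  }, numeric(1L))
}

# ---- dispatch + mixtures ---------------------------------------------------

#' Intensity contribution of one species
#'
#' Generic dispatcher used by [mixture_intensity()]: routes to
#' [cylinder_intensity()], [wormlike_intensity()], [sphere_form_factor()]
#' (times scale) or [debye_intensity_from_structure()] (times scale).
#'
#' @param q Momentum transfer grid, \eqn{\mathrm{\AA}^{-1}}.
#' @param species A [saxs_species] object.
#' @return Intensity vector, \eqn{cm^{-1}}.
#' @export
species_intensity <- function(q, species) {
  UseMethod("species_intensity", species)
}

#' @export
species_intensity.cylinder_species <- function(q, species)
  cylinder_intensity(q, species)

#' @export
species_intensity.wormlike_species <- function(q, species)
  wormlike_intensity(q, species)

#' @export
species_intensity.sphere_species <- function(q, species)
  species$scale * sphere_form_factor(q, species$radius)

#' @export
species_intensity.atomic_structure <- function(q, species)
  species$scale * debye_intensity_from_structure(q, species)

#' Mixture intensity
#'
#' Dilute-limit model curve: point-wise sum of the per-species
#' contributions plus the flat background. Linear in every species scale.
#'
#' @param q Momentum transfer grid, \eqn{\mathrm{\AA}^{-1}}.
#' @param mixture A [species_mixture()].
#' @param label Label for the returned curve.
#' @return A [saxs_curve()] (no uncertainty column).
#' @examples
#' mix <- species_mixture(cylinder_species(40, 2000, scale = 2),
#'                        background = 0.001)
#' mixture_intensity(seq(0.005, 0.2, length.out = 30), mix)
#' @export
mixture_intensity <- function(q, mixture, label = "model") {
  stopifnot(inherits(mixture, "species_mixture"))
  total <- rep(mixture$background, length(q))
  for (s in mixture$species) total <- total + species_intensity(q, s)
  saxs_curve(q, total, label = label)
}
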