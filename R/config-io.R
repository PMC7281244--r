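# YAML/JSON configuration for mixture fits and JSON export of results.

param_from_cfg <- function(x, default) {
  # a parameter entry is either a bare number (fixed) or a map with
  # value / free / lower / upper
  if (is.null(x)) return(list(value = default, free = FALSE))
  if (is.numeric(x) && length(x) == 1L)
    return(list(value = as.numeric(x), free = FALSE))
  if (is.list(x)) {
    v <- if (is.null(x$value)) default else as.numeric(x$value)
    free <- isTRUE(x$free)
    if (free && (is.null(x$lower) || is.null(x$upper)))
      stop("free parameters need finite 'lower' and 'upper' bounds")
    return(list(value = v, free = free,
                lower = if (free) as.numeric(x$lower),
                upper = if (free) as.numeric(x$upper)))
  }
  stop("cannot interpret parameter entry of class ", class(x)[1L])
}

#' Read a mixture-fit specification from YAML or JSON
#'
#' The configuration maps directly onto [fit_spec()]: a `species` list
#' (each with a `type` - `cylinder`, `wormlike` or `sphere` - and its
#' parameters), a `background` entry and a `seed`. A parameter given as a
#' bare number is fixed; a map `{value, free: true, lower, upper}`
#' declares it free.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [fit_spec()].
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c(
#'   "seed: 5",
#'   "background: {value: 0.001, free: true, lower: 0, upper: 0.1}",
#'   "species:",
#'   "  - type: cylinder",
#'   "    radius: {value: 50, free: true, lower: 15, upper: 90}",
#'   "    length: 2000",
#'   "    polydispersity: 0.2",
#'   "    scale: {value: 1, free: true, lower: 0, upper: 10}"), cfg)
#' read_fit_spec(cfg)
#' @export
read_fit_spec <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  if (is.null(cfg$species) || !length(cfg$species))
    stop("config must declare at least one species")
  defaults <- list(
    cylinder = list(radius = 40, length = 2000, polydispersity = 0,
                    scale = 1),
    wormlike = list(contour_length = 400, kuhn_length = 40,
                    cross_radius = 0, aggregation_number = 1, scale = 1),
    sphere = list(radius = 20, scale = 1))
  free <- list()
  species <- vector("list", length(cfg$species))
  for (i in seq_along(cfg$species)) {
    sc <- cfg$species[[i]]
    type <- match.arg(sc$type, names(defaults))
    vals <- defaults[[type]]
    for (fname in names(vals)) {
      p <- param_from_cfg(sc[[fname]], vals[[fname]])
      vals[[fname]] <- p$value
      if (p$free)
        free[[paste0("species", i, ".", fname)]] <-
          c(init = p$value, lower = p$lower, upper = p$upper)
    }
    species[[i]] <- do.call(switch(type, cylinder = cylinder_species,
                                   wormlike = wormlike_species,
                                   sphere = sphere_species),
                            vals)
  }
  bg <- param_from_cfg(cfg$background, 0)
  mix <- species_mixture(species, background = bg$value)
  if (bg$free)
    free$background <- c(init = bg$value, lower = bg$lower,
                         upper = bg$upper)
  fit_spec(mix, free = free,
           seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
}

#' Export fit results as JSON
#'
#' Writers for the portable result records: a mixture fit (parameters,
#' uncertainties, reduced chi-square, species fractions, convergence), a
#' Guinier fit (kind, size, forward intensity, window, goodness) or a
#' sigmoid kinetics fit.
#'
#' @param x A `"mixture_fit"`, `"guinier_fit"` or `"sigmoid_fit"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  rec <- result_record(x)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

result_record <- function(x) UseMethod("result_record")

#' @export
result_record.mixture_fit <- function(x) {
  list(type = "mixture_fit",
       parameters = lapply(seq_len(nrow(x$best_parameters)), function(i)
         list(name = rownames(x$best_parameters)[i],
              estimate = x$best_parameters$estimate[i],
              se = x$best_parameters$se[i])),
       chi2_reduced = x$chi2_reduced,
       species_fractions = as.list(x$species_fractions),
       pinned = as.list(x$pinned),
       convergence = x$convergence[c("status", "message", "iterations")])
}

#' @export
result_record.guinier_fit <- function(x) {
  list(type = "guinier_fit", kind = x$kind, size = x$size,
       forward = x$forward,
       q_range = list(qmin = x$q_range[1L], qmax = x$q_range[2L]),
       r_squared = x$r_squared, n_points = x$n_points)
}

#' @export
result_record.sigmoid_fit <- function(x) {
  list(type = "sigmoid_fit", model = x$model, baseline = x$baseline,
       plateau = x$plateau, t_half = x$t_half, rate = x$rate,
       lag_time = x$lag_time, residual_rms = x$residual_rms,
       censored = x$censored)
}
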