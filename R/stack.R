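#' Define one planar tissue layer
#'
#' A layer couples a thickness with an optical-property spectrum.  The
#' spectrum is a data frame with columns `wavelength_nm`, `mu_a`,
#' `mu_s_prime` and optionally `g` (default 0) and `n` (default `NA`,
#' meaning "use the stack's shared refractive-index table").  Properties
#' are interpolated piecewise-linearly in wavelength at simulation time.
#'
#' @param name layer label
#' @param thickness layer thickness in mm; `Inf` only for a terminal
#'   (deepest) semi-infinite layer
#' @param spectrum optical-property spectrum (see Details)
#' @return an object of class `uv_layer`
#' @export
layer <- function(name, thickness, spectrum) {
  if (!is.character(name) || length(name) != 1L) stop("'name' must be a string", call. = FALSE)
  if (!is.numeric(thickness) || length(thickness) != 1L || is.na(thickness) || thickness <= 0)
    stop("'thickness' must be a positive number (possibly Inf)", call. = FALSE)
  spectrum <- as_spectrum(spectrum)
  structure(list(name = name, thickness = thickness, spectrum = spectrum),
            class = "uv_layer")
}

# normalize a spectrum data frame to internal columns
as_spectrum <- function(x) {
  x <- as.data.frame(x)
  need <- c("wavelength_nm", "mu_a", "mu_s_prime")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("spectrum is missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(x$g)) x$g <- 0
  if (is.null(x$n)) x$n <- NA_real_
  if (any(!is.finite(x$wavelength_nm))) stop("non-finite wavelength in spectrum", call. = FALSE)
  bad <- which(x$mu_a < 0 | x$mu_s_prime < 0)
  if (length(bad))
    stop("negative coefficient in spectrum at row ", bad[1], call. = FALSE)
  if (any(x$g <= -1 | x$g >= 1)) stop("anisotropy in spectrum must satisfy -1 < g < 1", call. = FALSE)
  o <- order(x$wavelength_nm)
  x <- x[o, c("wavelength_nm", "mu_a", "mu_s_prime", "g", "n"), drop = FALSE]
  if (anyDuplicated(x$wavelength_nm)) stop("duplicate wavelengths in spectrum", call. = FALSE)
  rownames(x) <- NULL
  x
}

#' Assemble planar layers into a cornea-style stack
#'
#' Layers are ordered top (irradiated surface, z = 0) to bottom; z grows
#' downward and interfaces sit at cumulative thickness sums.  Only the last
#' layer may be semi-infinite.  `boundary_mode` selects how photons that
#' reach the top surface from below are treated: `"fresnel"` applies the
#' usual Fresnel escape/internal-reflection draw; `"mirror_top"`
#' deterministically reflects them back into the tissue (a mirror boundary).
#'
#' @param layers list of [layer()] objects, top first
#' @param n_above,n_below refractive indices of the ambient media above and
#'   below the stack (air = 1)
#' @param boundary_mode `"fresnel"` or `"mirror_top"`
#' @param n_table optional shared `(wavelength, n)` table used for layers
#'   whose spectra carry no refractive index
#' @return an object of class `layer_stack`
#' @examples
#' sp <- data.frame(wavelength_nm = c(200, 300), mu_a = c(5, 5), mu_s_prime = c(20, 20))
#' st <- layer_stack(list(layer("slab", 0.04, sp)), n_above = 1, n_below = 1)
#' @export
layer_stack <- function(layers, n_above = 1, n_below = 1,
                        boundary_mode = c("fresnel", "mirror_top"),
                        n_table = NULL) {
  boundary_mode <- match.arg(boundary_mode)
  if (!is.list(layers) || !length(layers) || !all(vapply(layers, inherits, TRUE, "uv_layer")))
    stop("'layers' must be a non-empty list of layer() objects", call. = FALSE)
  th <- vapply(layers, function(l) l$thickness, 0)
  if (any(!is.finite(th[-length(th)])))
    stop("only the last (deepest) layer may be semi-infinite", call. = FALSE)
  stopifnot_scalar(n_above, "n_above"); stopifnot_scalar(n_below, "n_below")
  if (n_above < 1 || n_below < 1) stop("ambient refractive indices must be >= 1", call. = FALSE)
  structure(list(layers = layers, n_above = n_above, n_below = n_below,
                 boundary_mode = boundary_mode, n_table = n_table),
            class = "layer_stack")
}

#' Depths of the layer interfaces of a stack
#'
#' @param stack a [layer_stack()]
#' @return named numeric vector of interface depths (mm): the lower
#'   boundary of every finite layer, named after the layer above it
#' @export
interface_depths <- function(stack) {
  stopifnot(inherits(stack, "layer_stack"))
  th <- vapply(stack$layers, function(l) l$thickness, 0)
  nm <- vapply(stack$layers, function(l) l$name, "")
  z <- cumsum(th)
  fin <- is.finite(z)
  setNames(z[fin], nm[fin])
}

#' @export
print.layer_stack <- function(x, ...) {
  th <- vapply(x$layers, function(l) l$thickness, 0)
  nm <- vapply(x$layers, function(l) l$name, "")
  cat(sprintf("layer stack (%d layer%s, boundary: %s)\n", length(nm),
              if (length(nm) > 1) "s" else "", x$boundary_mode))
  for (i in seq_along(nm)) {
    rng <- range(x$layers[[i]]$spectrum$wavelength_nm)
    cat(sprintf("  %d. %-12s %8s mm   [%g-%g nm]\n", i, nm[i],
                if (is.finite(th[i])) format(th[i]) else "Inf", rng[1], rng[2]))
  }
  cat(sprintf("  ambient n: %g above, %g below\n", x$n_above, x$n_below))
  invisible(x)
}

# Resolve per-layer (thickness, mu_a, mu_s, g, n) at one wavelength.
# Zero-thickness layers were never constructed (layer() forbids them), but
# degenerate layers may be dropped upstream by build_cornea().
resolve_stack <- function(stack, wavelength) {
  lst <- lapply(stack$layers, function(l) {
    sp <- l$spectrum
    rng <- range(sp$wavelength_nm)
    if (wavelength < rng[1] || wavelength > rng[2])
      stop(sprintf("layer '%s' has no optical properties at %g nm (covers %g-%g nm)",
                   l$name, wavelength, rng[1], rng[2]), call. = FALSE)
    mu_a <- approx(sp$wavelength_nm, sp$mu_a, wavelength)$y
    msp <- approx(sp$wavelength_nm, sp$mu_s_prime, wavelength)$y
    g <- approx(sp$wavelength_nm, sp$g, wavelength)$y
    n <- if (all(is.na(sp$n))) {
      if (is.null(stack$n_table))
        stop(sprintf("layer '%s' has no refractive index and the stack has no shared n table",
                     l$name), call. = FALSE)
      interpolate_refractive_index(stack$n_table, wavelength)
    } else approx(sp$wavelength_nm, sp$n, wavelength)$y
    c(thickness = l$thickness, mu_a = mu_a, mu_s = msp / (1 - g), g = g, n = n)
  })
  m <- do.call(rbind, lst)
  rownames(m) <- vapply(stack$layers, function(l) l$name, "")
  m
}

#' Monte Carlo simulation configuration
#'
#' @param n_photons number of photon packets to launch
#' @param seed RNG seed (mandatory; there is no silent default)
#' @param dz depth-bin width, mm
#' @param z_max maximum recorded depth, mm
#' @param roulette_threshold packet weight below which Russian roulette runs
#' @param roulette_survival roulette survival probability (weight is divided
#'   by this on survival, keeping the walk unbiased)
#' @param beam beam model; only an infinitely broad collimated
#'   normal-incidence beam is implemented
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_photons = 1e5, seed, dz = 0.001, z_max = 0.6,
                       roulette_threshold = 1e-4, roulette_survival = 0.1,
                       beam = "collimated_normal") {
  if (missing(seed)) stop("'seed' is mandatory in sim_config(); none is assumed", call. = FALSE)
  stopifnot_scalar(n_photons, "n_photons", positive = TRUE)
  stopifnot_scalar(seed, "seed")
  stopifnot_scalar(dz, "dz", positive = TRUE)
  stopifnot_scalar(z_max, "z_max", positive = TRUE)
  if (dz > z_max) stop("'dz' must not exceed 'z_max'", call. = FALSE)
  stopifnot_scalar(roulette_threshold, "roulette_threshold", positive = TRUE)
  stopifnot_scalar(roulette_survival, "roulette_survival")
  if (roulette_survival <= 0 || roulette_survival >= 1)
    stop("'roulette_survival' must lie strictly in (0, 1)", call. = FALSE)
  beam <- match.arg(beam, "collimated_normal")
  structure(list(n_photons = as.integer(n_photons), seed = as.integer(seed),
                 dz = dz, z_max = z_max,
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival, beam = beam),
            class = "sim_config")
}
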