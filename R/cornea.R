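#' Cornea geometry presets
#'
#' The three layered cornea geometries used throughout the package:
#' a porcine cornea (110 um epithelium), a human cornea with a thin,
#' non-intact epithelium (26 um), and an intact human cornea (50 um) —
#' each under a 5 um tear film and above a semi-infinite stroma.
#'
#' @param name one of `"porcine"`, `"human_thin"`, `"human_intact"`
#' @param tear_um,epithelium_um thickness overrides in micrometres; a zero
#'   thickness drops the layer
#' @return list of class `cornea_preset` with thicknesses in um
#' @examples
#' cornea_preset("human_intact")
#' @export
cornea_preset <- function(name = c("porcine", "human_thin", "human_intact"),
                          tear_um = 5, epithelium_um = NULL) {
  name <- match.arg(name)
  if (is.null(epithelium_um))
    epithelium_um <- c(porcine = 110, human_thin = 26, human_intact = 50)[[name]]
  if (tear_um < 0 || epithelium_um < 0) stop("thicknesses must be >= 0", call. = FALSE)
  structure(list(name = name, tear_um = tear_um, epithelium_um = epithelium_um,
                 stroma = Inf),
            class = "cornea_preset")
}

#' @export
print.cornea_preset <- function(x, ...) {
  cat(sprintf("cornea preset '%s': tear %g um | epithelium %g um | stroma Inf\n",
              x$name, x$tear_um, x$epithelium_um))
  invisible(x)
}

#' Convert a decadic absorbance to an absorption coefficient
#'
#' `mu_a = ln(10) * A / path`, for an absorbance `A` measured over a path
#' length in mm.  Used to turn a tear-fluid absorbance spectrum (measured
#' in a cuvette) into the tear film's `mu_a(lambda)`.
#'
#' @param absorbance decadic absorbance (dimensionless), >= 0
#' @param path_mm optical path length of the measurement, mm, > 0
#' @return absorption coefficient(s), mm^-1
#' @examples
#' absorbance_to_mu_a(1, 10)   # 0.2303 mm^-1
#' @export
absorbance_to_mu_a <- function(absorbance, path_mm) {
  stopifnot_scalar(path_mm, "path_mm", positive = TRUE)
  if (any(absorbance < 0)) stop("'absorbance' must be >= 0", call. = FALSE)
  log(10) * absorbance / path_mm
}

#' Built-in synthetic corneal refractive-index table
#'
#' A plausible water-like decreasing course offset to the corneal index,
#' shipped as a replaceable CSV.  It is a synthetic stand-in: the
#' literature UV values it emulates are published only as figures.
#'
#' @return data frame `wavelength_nm`, `n`
#' @export
default_refractive_index <- function() {
  path <- system.file("extdata", "cornea_refractive_index_synthetic.csv",
                      package = "corneauv", mustWork = TRUE)
  read.csv(path)
}

#' Built-in synthetic tear-film absorption spectrum
#'
#' Tear-fluid absorbance per 10 mm path with a strong rise below 240 nm
#' (protein and ascorbate absorption), converted to `mu_a` of the tear
#' film.  Synthetic stand-in for an unpublished measured spectrum; the
#' tear film is treated as non-scattering (`mu_s' = 0`).
#'
#' @return spectrum data frame `wavelength_nm`, `mu_a`, `mu_s_prime`
#' @export
default_tear_spectrum <- function() {
  path <- system.file("extdata", "tear_absorbance_synthetic.csv",
                      package = "corneauv", mustWork = TRUE)
  tab <- read.csv(path)
  data.frame(wavelength_nm = tab$wavelength_nm,
             mu_a = absorbance_to_mu_a(tab$absorbance, tab$path_mm[1]),
             mu_s_prime = 0)
}

#' Build a layered cornea model
#'
#' Assembles the `[tear, epithelium, stroma(Inf)]` stack for a preset,
#' attaching per-layer optical spectra and a shared refractive-index
#' table; z = 0 is the tear surface.  Degenerate (zero-thickness) layers
#' are dropped.  The human presets are intended to be driven with the
#' porcine layer spectra, mirroring how an intact-cornea prediction is
#' made when only porcine sections can be measured.
#'
#' @param preset a [cornea_preset()] or preset name
#' @param epithelium_spectrum,stroma_spectrum spectra covering the
#'   requested band (columns `wavelength_nm`, `mu_a`, `mu_s_prime`,
#'   optional `g`, `n`)
#' @param tear_spectrum tear-film spectrum; default [default_tear_spectrum()]
#' @param boundary_mode `"mirror_top"` (penetration geometry default) or
#'   `"fresnel"`
#' @param n_table shared `(wavelength, n)` table; default
#'   [default_refractive_index()].  With one shared index the inter-layer
#'   Fresnel events vanish, leaving only the air/tear surface.
#' @param band wavelength band (nm) every layer spectrum must cover; a
#'   spectral gap over this band fails construction early
#' @return a [layer_stack()]
#' @examples
#' sp <- synth_optical_spectra(spectrum_params("epithelium"))
#' st <- build_cornea("porcine", sp, synth_optical_spectra(spectrum_params("stroma")))
#' interface_depths(st)   # 0.005 and 0.115 mm
#' @export
build_cornea <- function(preset, epithelium_spectrum, stroma_spectrum,
                         tear_spectrum = default_tear_spectrum(),
                         boundary_mode = c("mirror_top", "fresnel"),
                         n_table = default_refractive_index(),
                         band = c(200, 300)) {
  if (is.character(preset)) preset <- cornea_preset(preset)
  stopifnot(inherits(preset, "cornea_preset"))
  boundary_mode <- match.arg(boundary_mode)
  layers <- list()
  if (preset$tear_um > 0)
    layers <- c(layers, list(layer("tear", preset$tear_um / 1000, tear_spectrum)))
  if (preset$epithelium_um > 0)
    layers <- c(layers, list(layer("epithelium", preset$epithelium_um / 1000,
                                   epithelium_spectrum)))
  layers <- c(layers, list(layer("stroma", Inf, stroma_spectrum)))
  st <- layer_stack(layers, n_above = 1, n_below = 1,
                    boundary_mode = boundary_mode, n_table = n_table)
  # fail early on spectral gaps over the working band
  cov <- vapply(layers, function(l) range(l$spectrum$wavelength_nm), c(0, 0))
  if (max(cov[1, ]) > band[1] || min(cov[2, ]) < band[2])
    stop(sprintf(
      "layer spectra must cover %g-%g nm; narrowest layer covers %g-%g nm",
      band[1], band[2], max(cov[1, ]), min(cov[2, ])), call. = FALSE)
  st
}
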