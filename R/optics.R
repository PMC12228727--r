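#' Optical properties of a tissue layer at one wavelength
#'
#' Bundles the absorption coefficient, scattering coefficient, scattering
#' anisotropy and refractive index of a homogeneous medium.  All
#' coefficients are in mm^-1.  The reduced (effective) scattering
#' coefficient is `mu_s * (1 - g)`; when only a reduced coefficient is
#' known, use `g = 0` and `mu_s = mu_s_prime` (the similarity relation).
#'
#' @param mu_a absorption coefficient (mm^-1), >= 0
#' @param mu_s scattering coefficient (mm^-1), >= 0
#' @param g scattering anisotropy (mean deflection cosine), -1 < g < 1
#' @param n refractive index, >= 1
#' @return an object of class `optical_properties`
#' @examples
#' op <- optical_properties(mu_a = 5, mu_s = 20, g = 0, n = 1.376)
#' mu_s_prime(op)
#' @export
optical_properties <- function(mu_a, mu_s, g = 0, n = 1.376) {
  stopifnot_scalar(mu_a, "mu_a", nonneg = TRUE)
  stopifnot_scalar(mu_s, "mu_s", nonneg = TRUE)
  stopifnot_scalar(g, "g")
  if (g <= -1 || g >= 1) stop("anisotropy 'g' must satisfy -1 < g < 1", call. = FALSE)
  stopifnot_scalar(n, "n")
  if (n < 1) stop("refractive index 'n' must be >= 1", call. = FALSE)
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n),
            class = "optical_properties")
}

#' Reduced scattering coefficient
#'
#' @param x an `optical_properties` object
#' @return `mu_s * (1 - g)` in mm^-1
#' @export
mu_s_prime <- function(x) {
  stopifnot(inherits(x, "optical_properties"))
  x$mu_s * (1 - x$g)
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "optical properties: mu_a = %g mm^-1, mu_s = %g mm^-1 (mu_s' = %g), g = %g, n = %g\n",
    x$mu_a, x$mu_s, mu_s_prime(x), x$g, x$n))
  invisible(x)
}

#' Sample an exponential free-path length
#'
#' Inverse-CDF sampling of the photon step between interaction sites in a
#' medium of total attenuation `mu_t = mu_a + mu_s`.  A zero `mu_t`
#' (ballistic, non-interacting layer) yields an infinite step, which the
#' transport kernel interprets as "fly to the next boundary".
#'
#' @param mu_t total attenuation coefficient (mm^-1), >= 0
#' @param u uniform(0,1) variate(s)
#' @return step length(s) in mm; `Inf` when `mu_t = 0`
#' @examples
#' sample_step(1, exp(-1))   # 1 mm
#' @export
sample_step <- function(mu_t, u) {
  stopifnot_scalar(mu_t, "mu_t", nonneg = TRUE)
  if (any(u <= 0 | u >= 1)) stop("'u' must lie strictly in (0, 1)", call. = FALSE)
  if (mu_t == 0) return(rep(Inf, length(u)))
  -log(u) / mu_t
}

#' Sample a Henyey-Greenstein deflection cosine
#'
#' Closed-form inverse-CDF sampling of the scattering deflection cosine
#' under the Henyey-Greenstein phase function with mean cosine `g`; `g = 0`
#' is isotropic scattering.
#'
#' @param g anisotropy, -1 < g < 1
#' @param u uniform(0,1) variate(s)
#' @return deflection cosine(s) in `[-1, 1]`
#' @examples
#' sample_hg_cosine(0, 0.75)   # 0.5
#' @export
sample_hg_cosine <- function(g, u) {
  stopifnot_scalar(g, "g")
  if (g <= -1 || g >= 1) stop("anisotropy 'g' must satisfy -1 < g < 1", call. = FALSE)
  if (any(u < 0 | u > 1)) stop("'u' must lie in [0, 1]", call. = FALSE)
  if (abs(g) < 1e-12) return(2 * u - 1)
  t <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - t^2) / (2 * g)))
}

#' Henyey-Greenstein phase-function density of the deflection cosine
#'
#' @param cos_theta deflection cosine(s)
#' @param g anisotropy
#' @return density values (normalized over `[-1, 1]`)
#' @export
hg_density <- function(cos_theta, g) {
  0.5 * (1 - g^2) / (1 + g^2 - 2 * g * cos_theta)^1.5
}

#' Unpolarized Fresnel reflectance at a planar interface
#'
#' Average of the s- and p-polarized Fresnel reflection coefficients for a
#' ray crossing from index `n_i` into `n_t` with incidence cosine
#' `cos_incident`.  Returns 1 at and beyond the critical angle and at
#' grazing incidence.
#'
#' @param n_i,n_t refractive indices of the incident and transmitting media
#' @param cos_incident cosine of the angle of incidence, in `[0, 1]`
#' @return reflection probability in `[0, 1]` (vectorized over `cos_incident`)
#' @examples
#' fresnel_reflectance(1, 1.5, 1)      # 0.04
#' fresnel_reflectance(1.5, 1, 0.5)    # 1: beyond the critical angle
#' @export
fresnel_reflectance <- function(n_i, n_t, cos_incident) {
  stopifnot_scalar(n_i, "n_i"); stopifnot_scalar(n_t, "n_t")
  if (n_i < 1 || n_t < 1) stop("refractive indices must be >= 1", call. = FALSE)
  ci <- cos_incident
  if (any(ci < 0 | ci > 1)) stop("'cos_incident' must lie in [0, 1]", call. = FALSE)
  if (n_i == n_t) return(rep(0, length(ci)))
  out <- numeric(length(ci))
  st <- n_i / n_t * sqrt(pmax(0, 1 - ci^2))
  tir <- st >= 1 | ci < 1e-12
  out[tir] <- 1
  ok <- !tir
  if (any(ok)) {
    ct <- sqrt(1 - st[ok]^2)
    rs <- ((n_i * ci[ok] - n_t * ct) / (n_i * ci[ok] + n_t * ct))^2
    rp <- ((n_i * ct - n_t * ci[ok]) / (n_i * ct + n_t * ci[ok]))^2
    out[ok] <- 0.5 * (rs + rp)
  }
  out
}

#' Interpolate (and linearly extrapolate) a refractive-index table
#'
#' Piecewise-linear interpolation of an `(wavelength, n)` table; outside
#' the table range the slope of the two nearest endpoints is continued
#' (linear extrapolation), matching how a UV refractive index is carried
#' beyond the last literature value.
#'
#' @param table data frame (or 2-column matrix) with wavelengths (nm) in
#'   the first column and refractive indices in the second, >= 2 rows
#' @param lambda query wavelength(s), nm
#' @return interpolated refractive index values
#' @examples
#' tab <- data.frame(wavelength_nm = c(200, 250), n = c(1.40, 1.38))
#' interpolate_refractive_index(tab, 225)   # 1.39
#' interpolate_refractive_index(tab, 300)   # 1.36 (extrapolated)
#' @export
interpolate_refractive_index <- function(table, lambda) {
  tab <- as.data.frame(table)
  if (ncol(tab) < 2 || nrow(tab) < 2)
    stop("refractive-index table needs >= 2 rows of (wavelength, n)", call. = FALSE)
  w <- as.numeric(tab[[1]]); n <- as.numeric(tab[[2]])
  o <- order(w); w <- w[o]; n <- n[o]
  if (anyDuplicated(w)) stop("duplicate wavelengths in refractive-index table", call. = FALSE)
  out <- approx(w, n, xout = lambda, rule = 1)$y
  k <- length(w)
  lo <- lambda < w[1]
  hi <- lambda > w[k]
  if (any(lo)) out[lo] <- n[1] + (n[2] - n[1]) / (w[2] - w[1]) * (lambda[lo] - w[1])
  if (any(hi)) out[hi] <- n[k] + (n[k] - n[k - 1]) / (w[k] - w[k - 1]) * (lambda[hi] - w[k])
  out
}
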