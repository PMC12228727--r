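#' Run a forward Monte Carlo transport simulation at one wavelength
#'
#' Launches `cfg$n_photons` photon packets at normal incidence onto the
#' stack and tallies specular and diffuse reflectance, total and ballistic
#' (unscattered) transmittance, absorbed fraction, and the depth-resolved
#' fluence.  Fluence is tallied with a weighted track-length estimator,
#' reported per unit incident power (the dimensionless ratio
#' `phi(z)/phi_incident`), which also covers non-absorbing layers where a
#' deposition-based estimator would be undefined.
#'
#' Runs are bit-reproducible: the same `cfg$seed` gives an identical
#' result, and the caller's RNG state is left untouched.
#'
#' @param stack a [layer_stack()]
#' @param wavelength wavelength in nm at which layer spectra are resolved
#' @param cfg a [sim_config()]
#' @param tally_fluence set `FALSE` to skip the depth tallies (faster; used
#'   in the inverse-model inner loop where only R/T are needed)
#' @return an object of class `transport_result`: fractions `R_specular`,
#'   `R_diffuse`, `T_total`, `T_ballistic`, `A_total`, Monte Carlo standard
#'   errors `se`, and a `fluence` data frame with bin-center depths `z_mm`
#'   and values `phi`
#' @examples
#' sp <- data.frame(wavelength_nm = c(200, 300), mu_a = 10, mu_s_prime = 0)
#' st <- layer_stack(list(layer("slab", 0.04, sp)), n_table = cbind(c(200, 300), c(1, 1)))
#' res <- run_forward_mc(st, 250, sim_config(n_photons = 2e4, seed = 1))
#' res$T_total   # close to exp(-0.4)
#' @export
run_forward_mc <- function(stack, wavelength, cfg, tally_fluence = TRUE) {
  stopifnot(inherits(stack, "layer_stack"), inherits(cfg, "sim_config"))
  stopifnot_scalar(wavelength, "wavelength")
  m <- resolve_stack(stack, wavelength)
  n_bins <- as.integer(round(cfg$z_max / cfg$dz))
  k <- with_seed(cfg$seed, .mc_kernel(
    thickness = m[, "thickness"], mu_a = m[, "mu_a"], mu_s = m[, "mu_s"],
    g = m[, "g"], n_layer = m[, "n"],
    n_above = stack$n_above, n_below = stack$n_below,
    mirror_top = identical(stack$boundary_mode, "mirror_top"),
    n_photons = cfg$n_photons, dz = cfg$dz, n_bins = n_bins,
    roulette_threshold = cfg$roulette_threshold,
    roulette_survival = cfg$roulette_survival,
    tally_fluence = tally_fluence))
  fl <- if (tally_fluence) {
    data.frame(z_mm = (seq_len(n_bins) - 0.5) * cfg$dz,
               phi = k$path / (cfg$dz * cfg$n_photons))
  } else NULL
  structure(list(
    wavelength = wavelength,
    R_specular = k$R_specular, R_diffuse = k$R_diffuse,
    T_total = k$T_total, T_ballistic = k$T_ballistic, A_total = k$A_total,
    se = list(R = k$se_R, T = k$se_T, A = k$se_A),
    fluence = fl, dep = if (tally_fluence) k$dep else NULL,
    n_photons = cfg$n_photons, dz = cfg$dz, seed = cfg$seed,
    boundary_mode = stack$boundary_mode,
    interfaces = interface_depths(stack)),
    class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf("transport result @ %g nm (%s photons, seed %d)\n",
              x$wavelength, format(x$n_photons, big.mark = ","), x$seed))
  cat(sprintf("  R_specular %.5f | R_diffuse %.5f (se %.1e)\n",
              x$R_specular, x$R_diffuse, x$se$R))
  cat(sprintf("  T_total    %.5f (se %.1e) | ballistic %.5f\n",
              x$T_total, x$se$T, x$T_ballistic))
  cat(sprintf("  A_total    %.5f (se %.1e)\n", x$A_total, x$se$A))
  bal <- x$R_specular + x$R_diffuse + x$T_total + x$A_total
  cat(sprintf("  energy balance: %.6f\n", bal))
  invisible(x)
}

#' Trace a single photon packet
#'
#' Runs the transport kernel for one packet and reports its terminal event
#' and the per-depth-bin absorbed weight.  Mostly a didactic / debugging
#' view of the hop-drop-spin walk; aggregate answers come from
#' [run_forward_mc()].
#'
#' @inheritParams run_forward_mc
#' @param seed RNG seed for this packet
#' @return list with `event` (one of `"reflected"`, `"transmitted"`,
#'   `"absorbed"`), `deposited` (data frame of bins with nonzero absorbed
#'   weight) and `weight_deposited` (its total)
#' @export
propagate_photon <- function(stack, wavelength, cfg, seed = cfg$seed) {
  cfg1 <- cfg
  cfg1$n_photons <- 1L
  cfg1$seed <- as.integer(seed)
  r <- run_forward_mc(stack, wavelength, cfg1)
  # the three terminal tallies are mutually exclusive for a single packet
  if (r$R_diffuse > 0) event <- "reflected"
  else if (r$T_total > 0) event <- "transmitted"
  else event <- "absorbed"
  nz <- which(r$dep > 0)
  list(event = event,
       deposited = data.frame(bin = nz - 1L,
                              z_mm = (nz - 0.5) * cfg$dz,
                              weight = r$dep[nz]),
       weight_deposited = sum(r$dep))
}
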