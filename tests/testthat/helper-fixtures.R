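# fixtures built in code: flat spectra, simple slabs, unit-index tables

unit_n <- cbind(wavelength_nm = c(100, 1000), n = c(1, 1))

flat_spectrum <- function(mu_a, mu_s_prime, g = 0, n = NA_real_) {
  data.frame(wavelength_nm = c(100, 1000), mu_a = mu_a,
             mu_s_prime = mu_s_prime, g = g, n = n)
}

slab_stack <- function(mu_a, mu_s_prime, d, n = 1, g = 0,
                       boundary = "fresnel") {
  layer_stack(list(layer("slab", d, flat_spectrum(mu_a, mu_s_prime, g, n))),
              n_above = 1, n_below = 1, boundary_mode = boundary)
}

semi_inf_stack <- function(mu_a, mu_s_prime, n = 1, g = 0,
                           boundary = "fresnel") {
  layer_stack(list(layer("deep", Inf, flat_spectrum(mu_a, mu_s_prime, g, n))),
              n_above = 1, n_below = 1, boundary_mode = boundary)
}

# two-interface closed form for a lossless slab of index n in air
lossless_slab_R <- function(n) {
  r <- ((n - 1) / (n + 1))^2
  2 * r / (1 + r)
}

with_seed_local <- function(seed, code) withr::with_seed(seed, code)
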