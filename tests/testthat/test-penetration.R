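test_that("threshold depths on exponential profiles match the closed form", {
  z <- seq(0.0005, 0.2, by = 0.001)
  prof <- exp(-100 * z)
  expect_equal(depth_at_fraction(prof, 0.1, dz = 0.001), log(10) / 100,
               tolerance = 0.001 / (log(10) / 100))
  expect_equal(depth_at_fraction(prof, 1, dz = 0.001), 0)
  expect_error(depth_at_fraction(numeric(0), 0.5, dz = 0.001), "empty")
  # never crossed within the recorded depth
  expect_identical(depth_at_fraction(exp(-0.1 * z), 0.1, dz = 0.001), Inf)
})

test_that("an exact node at a bin center is returned as-is", {
  # profile hits exactly 0.5 at the third bin center (0.010 mm, dz = 0.004)
  prof <- c(1, 0.75, 0.5, 0.25)
  expect_equal(depth_at_fraction(prof, 0.5, dz = 0.004), 0.010)
})

test_that("damage interval matches the analytic band for a pure absorber", {
  z <- seq(0.0005, 0.3, by = 0.001)
  prof <- exp(-50 * z)
  dp <- predict_damage_depth(prof, c(0.3, 0.4), dz = 0.001)
  expect_equal(dp$depth_mm[dp$tau == 0.4], -log(0.4) / 50, tolerance = 0.06)
  expect_equal(dp$depth_mm[dp$tau == 0.3], -log(0.3) / 50, tolerance = 0.06)
  expect_lte(dp$depth_mm[dp$tau == 0.4], dp$depth_mm[dp$tau == 0.3])
  # degenerate band
  dp1 <- predict_damage_depth(prof, c(1, 1), dz = 0.001)
  expect_equal(dp1$depth_mm, c(0, 0))
})

test_that("threshold depth is monotone in tau", {
  z <- seq(0.0005, 0.3, by = 0.001)
  for (prof in list(exp(-30 * z), exp(-80 * z), 1 / (1 + 200 * z^1.5))) {
    d <- vapply(c(0.6, 0.4, 0.3, 0.1), function(t)
      depth_at_fraction(prof, t, dz = 0.001), 0)
    expect_true(all(diff(d) >= 0))
  }
})

test_that("simulated semi-infinite absorber reproduces -ln(tau)/mu_a", {
  st <- semi_inf_stack(50, 0)
  r <- run_forward_mc(st, 250, sim_config(1e5, seed = 23))
  for (tau in c(0.5, 0.1)) {
    expect_lt(abs(depth_at_fraction(r, tau) - (-log(tau) / 50)), 0.0015)
  }
})

test_that("scaling all absorption up never deepens the 10% depth", {
  cfg <- sim_config(5e4, seed = 29)
  epi <- synth_optical_spectra(spectrum_params("epithelium"))
  str <- synth_optical_spectra(spectrum_params("stroma"))
  dbl <- function(sp) transform(sp, mu_a = 2 * mu_a)
  z10 <- function(e, s) {
    r <- run_forward_mc(build_cornea("human_intact", e, s), 233, cfg)
    depth_at_fraction(r, 0.1)
  }
  expect_lte(z10(dbl(epi), dbl(str)), z10(epi, str))
})

test_that("wavelength sweeps are reproducible and labelled by interfaces", {
  epi <- synth_optical_spectra(spectrum_params("epithelium"))
  str <- synth_optical_spectra(spectrum_params("stroma"))
  st <- build_cornea("human_thin", epi, str)
  cfg <- sim_config(1e4, seed = 37)
  sw1 <- wavelength_sweep(st, c(222, 254), cfg)
  sw2 <- wavelength_sweep(st, c(222, 254), cfg)
  expect_identical(as.data.frame(sw1), as.data.frame(sw2))
  expect_named(sw1, c("wavelength_nm", "z10_mm", "z1e_mm",
                      "frac_at_tear_base", "frac_at_epithelium_base"))
  expect_true(all(sw1$z1e_mm <= sw1$z10_mm))
  expect_true(all(sw1$frac_at_tear_base >= sw1$frac_at_epithelium_base))
})

test_that("damage depths are labelled with the layer they fall in", {
  spectra <- synth_scenario_spectra("epithelium_dominant")
  st <- build_cornea("human_thin", spectra$epithelium, spectra$stroma)
  r <- run_forward_mc(st, 233, sim_config(5e4, seed = 41))
  dp <- predict_damage_depth(r, c(0.3, 0.4), stack = st)
  expect_true(all(dp$layer %in% c("tear", "epithelium", "stroma")))
  # interval ordering holds with layers attached
  expect_lte(dp$depth_mm[dp$tau == 0.4], dp$depth_mm[dp$tau == 0.3])
})

test_that("comparison against observed depths flags overlap correctly", {
  obs <- observed_damage_depths()
  expect_named(obs, c("model", "source", "wavelength_nm", "observed_um", "sem_um"))
  expect_equal(nrow(obs), 5L)
  expect_true(all(c(27, 53, 166, 28, 71) %in% obs$observed_um))

  pred <- data.frame(model = c("human", "porcine", "porcine"),
                     wavelength_nm = c(233, 233, 254),
                     depth_min_mm = c(0.050, 0.010, Inf),
                     depth_max_mm = c(0.056, 0.015, Inf))
  rep <- compare_to_observed(pred, obs)
  expect_identical(rep$flag[rep$model == "human"], "overlap")
  expect_identical(rep$flag[rep$model == "porcine" & rep$wavelength_nm == 233],
                   "no_overlap")
  expect_identical(rep$flag[rep$wavelength_nm == 254], "not reached")

  empty <- compare_to_observed(pred[0, ], obs)
  expect_equal(nrow(empty), 0L)
})
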