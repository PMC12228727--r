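epi <- synth_optical_spectra(spectrum_params("epithelium"))
str <- synth_optical_spectra(spectrum_params("stroma"))

test_that("presets carry the standard layer thicknesses", {
  expect_equal(interface_depths(build_cornea("porcine", epi, str)),
               c(tear = 0.005, epithelium = 0.115))
  expect_equal(interface_depths(build_cornea("human_thin", epi, str)),
               c(tear = 0.005, epithelium = 0.031))
  expect_equal(interface_depths(build_cornea("human_intact", epi, str)),
               c(tear = 0.005, epithelium = 0.055))
})

test_that("degenerate layers are dropped without error", {
  p <- cornea_preset("porcine", epithelium_um = 0)
  st <- build_cornea(p, epi, str)
  expect_equal(length(st$layers), 2L)
  expect_equal(vapply(st$layers, function(l) l$name, ""), c("tear", "stroma"))
})

test_that("absorbance converts to an absorption coefficient", {
  expect_equal(absorbance_to_mu_a(1, 10), log(10) / 10)
  expect_equal(absorbance_to_mu_a(0, 10), 0)
  expect_equal(absorbance_to_mu_a(2, 1), 2 * log(10))
  expect_error(absorbance_to_mu_a(1, 0), "path")
})

test_that("tear film is a pure absorber rising below 240 nm", {
  tear <- default_tear_spectrum()
  expect_true(all(tear$mu_a >= 0))
  expect_true(all(tear$mu_s_prime == 0))
  expect_gt(tear$mu_a[tear$wavelength_nm == 210],
            5 * tear$mu_a[tear$wavelength_nm == 280])
})

test_that("removing the tear film never decreases intensity at depth", {
  cfg <- sim_config(5e4, seed = 31)
  with_tear <- build_cornea("human_thin", epi, str)
  without <- build_cornea(cornea_preset("human_thin", tear_um = 0), epi, str)
  r1 <- run_forward_mc(with_tear, 215, cfg)
  r0 <- run_forward_mc(without, 215, cfg)
  # compare fluence (per incident power) at matching tissue depths: depth z
  # below the epithelium surface sits at z + 0.005 mm when the 5 um tear
  # film is present and at z without it
  probe <- c(0.005, 0.015, 0.035)
  f1 <- approx(r1$fluence$z_mm, r1$fluence$phi, probe + 0.005)$y
  f0 <- approx(r0$fluence$z_mm, r0$fluence$phi, probe)$y
  expect_true(all(f0 >= f1 * 0.98))  # 2% MC slack
})

test_that("stack construction is pure and validates coverage", {
  a <- build_cornea("porcine", epi, str)
  b <- build_cornea("porcine", epi, str)
  expect_identical(a, b)
  short <- epi[epi$wavelength_nm >= 240, ]
  expect_error(build_cornea("porcine", short, str), "cover 200-300")
})

test_that("default refractive table interpolates inside 200-300 nm", {
  tab <- default_refractive_index()
  n <- interpolate_refractive_index(tab, c(222, 233, 254))
  expect_true(all(n > 1.3 & n < 1.5))
  expect_true(all(diff(n) < 0))  # normal dispersion: n falls with wavelength
})
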