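test_that("synthetic spectra have plateau, midpoint and tissue ordering", {
  p_epi <- spectrum_params("epithelium")
  p_str <- spectrum_params("stroma")
  epi <- synth_optical_spectra(p_epi)
  str <- synth_optical_spectra(p_str)

  # plateau at 300 nm: logistic term < 1e-3 of the amplitude
  expect_equal(epi$mu_a[epi$wavelength_nm == 300], p_epi$baseline_mu_a,
               tolerance = 1e-3)
  # exact midpoint at the onset wavelength
  expect_equal(epi$mu_a[epi$wavelength_nm == p_epi$rise_onset],
               p_epi$baseline_mu_a + p_epi$rise_amplitude_mu_a / 2)
  # stroma exceeds epithelium below the onset
  expect_gt(str$mu_a[str$wavelength_nm == 210],
            epi$mu_a[epi$wavelength_nm == 210])
  # reduced scattering above absorption everywhere, both tissues
  expect_true(all(epi$mu_s_prime > epi$mu_a))
  expect_true(all(str$mu_s_prime > str$mu_a))
  # deterministic
  expect_identical(epi, synth_optical_spectra(spectrum_params("epithelium")))
})

test_that("both scenario spectrum pairs satisfy their stated orderings", {
  for (sc in c("stroma_dominant", "epithelium_dominant")) {
    sp <- synth_scenario_spectra(sc)
    blw <- sp$epithelium$wavelength_nm < 240
    tot_epi <- sp$epithelium$mu_a + sp$epithelium$mu_s_prime
    tot_str <- sp$stroma$mu_a + sp$stroma$mu_s_prime
    if (sc == "stroma_dominant") {
      expect_true(all(sp$stroma$mu_a[blw] > sp$epithelium$mu_a[blw]))
      expect_true(all(sp$stroma$mu_s_prime[blw] > sp$epithelium$mu_s_prime[blw]))
    } else {
      expect_true(all(tot_epi[blw] > tot_str[blw]))
    }
    expect_true(all(sp$epithelium$mu_s_prime > sp$epithelium$mu_a))
    expect_true(all(sp$stroma$mu_s_prime > sp$stroma$mu_a))
  }
})

test_that("noise-free datasets equal the forward predictions exactly", {
  truth <- data.frame(wavelength_nm = c(250, 260), mu_a = 5, mu_s_prime = 20, g = 0)
  cfg <- sim_config(1e4, seed = 51)
  d <- synth_rt_dataset(truth, noise = noise_model(0, 0, seed = 3), cfg = cfg)
  for (i in 1:2) {
    rt <- forward_rt_thin_section(5, 20, 0.04, 1.376, cfg)
    expect_identical(d$measurements$R_total[i], rt[["R"]])
    expect_identical(d$measurements$T_total[i], rt[["T"]])
  }
  expect_identical(d$n_clipped, 0L)
})

test_that("replicate noise has the configured scale and stays physical", {
  truth <- synth_optical_spectra(spectrum_params("epithelium"),
                                 seq(240, 300, 10))
  cfg <- sim_config(1e4, seed = 52)
  d <- synth_rt_dataset(truth, noise = noise_model(0.005, 0.005, seed = 7),
                        k_replicates = 5, cfg = cfg)
  sds <- vapply(split(d$measurements$T_total, d$measurements$wavelength_nm), sd, 0)
  # sd of an sd estimate at k = 5 is ~ sigma/sqrt(2(k-1))
  expect_true(all(abs(sds - 0.005) < 3 * 0.005 / sqrt(8)))
  expect_true(all(d$measurements$R_total + d$measurements$T_total <= 1))
  expect_true(all(d$measurements$R_total >= 0 & d$measurements$T_total >= 0))

  # heavy noise forces clipping, which is counted
  dbig <- synth_rt_dataset(truth, noise = noise_model(0.3, 0.3, seed = 8),
                           k_replicates = 3, cfg = cfg)
  expect_gt(dbig$n_clipped, 0)
  expect_true(all(dbig$measurements$R_total + dbig$measurements$T_total <= 1))
})

test_that("generator is deterministic in seed, truth independent of noise seed", {
  truth <- data.frame(wavelength_nm = 250, mu_a = 5, mu_s_prime = 20, g = 0)
  cfg <- sim_config(1e4, seed = 53)
  d1 <- synth_rt_dataset(truth, noise = noise_model(0.005, 0.005, seed = 9), cfg = cfg)
  d2 <- synth_rt_dataset(truth, noise = noise_model(0.005, 0.005, seed = 9), cfg = cfg)
  d3 <- synth_rt_dataset(truth, noise = noise_model(0.005, 0.005, seed = 10), cfg = cfg)
  expect_identical(d1$measurements, d2$measurements)
  expect_false(identical(d1$measurements$R_total, d3$measurements$R_total))
  expect_identical(d1$truth, d3$truth)
})

test_that("recovery scoring is exact on perfect estimates and bookkeeps", {
  truth <- synth_optical_spectra(spectrum_params("epithelium"), c(250, 260, 270))
  perfect <- data.frame(wavelength_nm = truth$wavelength_nm,
                        mu_a = truth$mu_a, mu_s_prime = truth$mu_s_prime)
  sc <- recovery_score(perfect, truth)
  expect_equal(unname(sc$median_rel_error), c(0, 0))
  expect_equal(unname(sc$max_rel_error), c(0, 0))

  # a bin with no converged replicate is excluded and counted
  tab <- cbind(perfect, n_converged = c(1, 0, 1), n_rep = 1)
  tab$mu_a[2] <- 99
  sc2 <- recovery_score(tab, truth)
  expect_identical(sc2$n_excluded, 1L)
  expect_equal(unname(sc2$max_rel_error[["mu_a"]]), 0)
})
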