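cfg_fast <- sim_config(n_photons = 2e4, seed = 11)

test_that("degenerate slabs produce the trivial terminal events", {
  # clear matched slab: everything transmits at full weight
  st <- slab_stack(0, 0, 0.04)
  r <- run_forward_mc(st, 250, cfg_fast)
  expect_equal(r$T_total, 1)
  expect_equal(r$R_specular + r$R_diffuse, 0)
  expect_equal(r$A_total, 0)
  p <- propagate_photon(st, 250, cfg_fast, seed = 3)
  expect_identical(p$event, "transmitted")

  # semi-infinite pure absorber: everything is deposited
  st2 <- semi_inf_stack(10, 0)
  r2 <- run_forward_mc(st2, 250, cfg_fast)
  expect_equal(r2$T_total, 0)
  expect_equal(r2$R_diffuse, 0)
  expect_equal(r2$A_total, 1, tolerance = 1e-6)
  p2 <- propagate_photon(st2, 250, cfg_fast, seed = 3)
  expect_identical(p2$event, "absorbed")
  expect_equal(p2$weight_deposited, 1, tolerance = 1e-9)
})

test_that("absorbing slab transmittance follows Beer-Lambert", {
  st <- slab_stack(10, 0, 0.04)
  cfg <- sim_config(n_photons = 1e5, seed = 42)
  r <- run_forward_mc(st, 250, cfg)
  expect_lt(abs(r$T_total - exp(-0.4)), 3 * r$se$T)
  expect_gt(r$se$T, 0)
})

test_that("ballistic transmittance of a scattering slab follows attenuation law", {
  st <- slab_stack(5, 20, 0.04)
  cfg <- sim_config(n_photons = 1e5, seed = 43)
  r <- run_forward_mc(st, 250, cfg)
  expected <- exp(-(5 + 20) * 0.04)
  se <- sqrt(expected * (1 - expected) / cfg$n_photons)
  expect_lt(abs(r$T_ballistic - expected), 3 * se)
  # total transmittance exceeds ballistic (scattered light also exits)
  expect_gt(r$T_total, r$T_ballistic)
})

test_that("lossless mismatched slab reflects the multiple-reflection closed form", {
  st <- slab_stack(0, 0, 0.04, n = 1.376)
  cfg <- sim_config(n_photons = 1e5, seed = 44)
  r <- run_forward_mc(st, 250, cfg)
  R <- r$R_specular + r$R_diffuse
  expect_equal(R + r$T_total, 1, tolerance = 1e-12)
  expect_lt(abs(R - lossless_slab_R(1.376)), 4 * sqrt(R * (1 - R) / cfg$n_photons))
})

test_that("energy is conserved across randomized stacks", {
  set.seed(77)
  for (i in 1:25) {
    n_layers <- sample(1:3, 1)
    layers <- lapply(seq_len(n_layers), function(j)
      layer(paste0("L", j), runif(1, 0.01, 0.15),
            flat_spectrum(runif(1, 0.1, 30), runif(1, 0, 50),
                          g = runif(1, 0, 0.9), n = runif(1, 1.3, 1.5))))
    if (i %% 5 == 0)  # some stacks end in a semi-infinite absorber
      layers[[n_layers]] <- layer("deep", Inf,
                                  flat_spectrum(runif(1, 0.5, 20), runif(1, 0, 30),
                                                n = runif(1, 1.3, 1.5)))
    st <- layer_stack(layers, n_above = 1, n_below = 1)
    r <- run_forward_mc(st, 250, sim_config(2e4, seed = 1000 + i),
                        tally_fluence = FALSE)
    bal <- r$R_specular + r$R_diffuse + r$T_total + r$A_total
    expect_lt(abs(bal - 1), 1e-3)
  }
})

test_that("transmittance decreases monotonically with absorption", {
  t_vals <- vapply(c(1, 5, 20), function(mu_a) {
    run_forward_mc(slab_stack(mu_a, 10, 0.04), 250, cfg_fast)$T_total
  }, 0)
  expect_true(all(diff(t_vals) < 0))
})

test_that("fluence of a semi-infinite absorber decays as exp(-mu_a z)", {
  st <- semi_inf_stack(50, 0)
  r <- run_forward_mc(st, 250, sim_config(1e5, seed = 8))
  phi <- r$fluence$phi
  z <- r$fluence$z_mm
  keep <- z < 0.08  # ~98% attenuation range
  expect_true(all(diff(phi[keep]) <= 0))
  core <- z < 0.05
  expect_equal(phi[core], exp(-50 * z[core]), tolerance = 0.05)
})

test_that("mirror top boundary returns every upward photon", {
  st <- semi_inf_stack(5, 20, n = 1.376, boundary = "mirror_top")
  r <- run_forward_mc(st, 250, cfg_fast)
  expect_equal(r$R_diffuse, 0)
  expect_equal(r$R_specular + r$A_total, 1, tolerance = 1e-3)
  # fresnel mode lets diffuse light escape instead
  st2 <- semi_inf_stack(5, 20, n = 1.376, boundary = "fresnel")
  r2 <- run_forward_mc(st2, 250, cfg_fast)
  expect_gt(r2$R_diffuse, 0)
})

test_that("similarity relation: (mu_s, g) and (mu_s', 0) agree at high albedo", {
  # mu_s' = 80, mu_a = 2: albedo ratio 40 >= 10 and a few reduced mean free
  # paths across the section, where the similarity approximation applies
  cfg <- sim_config(n_photons = 5e4, seed = 9)
  r_g <- run_forward_mc(slab_stack(2, 80, 0.04, n = 1.376, g = 0.9), 250, cfg)
  r_0 <- run_forward_mc(slab_stack(2, 80, 0.04, n = 1.376, g = 0), 250, cfg)
  R_g <- r_g$R_specular + r_g$R_diffuse
  R_0 <- r_0$R_specular + r_0$R_diffuse
  expect_lt(abs(R_g - R_0) / R_0, 0.05)
  expect_lt(abs(r_g$T_total - r_0$T_total) / r_0$T_total, 0.05)
})

test_that("identical seeds reproduce bit-identical results", {
  st <- slab_stack(5, 20, 0.04, n = 1.376)
  r1 <- run_forward_mc(st, 250, cfg_fast)
  r2 <- run_forward_mc(st, 250, cfg_fast)
  expect_identical(r1, r2)
  r3 <- run_forward_mc(st, 250, sim_config(2e4, seed = 12))
  expect_false(identical(r1$T_total, r3$T_total))
})

test_that("missing spectral coverage raises an explicit error", {
  sp <- data.frame(wavelength_nm = c(240, 300), mu_a = 1, mu_s_prime = 1)
  st <- layer_stack(list(layer("slab", 0.04, sp)), n_table = unit_n)
  expect_error(run_forward_mc(st, 222, cfg_fast), "no optical properties at 222")
})

test_that("seed is mandatory and stack invariants are enforced", {
  expect_error(sim_config(1e4), "seed")
  expect_error(layer("bad", 0, flat_spectrum(1, 1)), "positive")
  expect_error(layer_stack(list(layer("a", Inf, flat_spectrum(1, 1)),
                                layer("b", 0.1, flat_spectrum(1, 1)))),
               "semi-infinite")
})
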