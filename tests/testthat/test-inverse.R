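cfg_inv <- sim_config(n_photons = 3e4, seed = 17)
cfg_meas <- sim_config(n_photons = 3e4, seed = 91)

test_that("thin-section forward model hits its closed-form limits", {
  # lossless mismatched slab: two-interface multiple-reflection formula
  rt <- forward_rt_thin_section(0, 0, 0.04, 1.376, cfg_inv)
  expect_equal(rt[["R"]], lossless_slab_R(1.376), tolerance = 0.02)
  expect_equal(rt[["R"]] + rt[["T"]], 1, tolerance = 1e-12)

  # matched-index pure absorber: Beer-Lambert
  rt2 <- forward_rt_thin_section(50, 0, 0.04, 1.0, cfg_inv)
  expect_equal(rt2[["R"]], 0)
  expect_lt(abs(rt2[["T"]] - exp(-2)), 3 * attr(rt2, "se")[["T"]])

  # lossless scatterer: conservation
  rt3 <- forward_rt_thin_section(0, 20, 0.04, 1.0, cfg_inv)
  expect_equal(rt3[["R"]] + rt3[["T"]], 1, tolerance = 1e-3)
})

test_that("the forward map is deterministic under common random numbers", {
  a <- forward_rt_thin_section(5, 20, 0.04, 1.376, cfg_inv)
  b <- forward_rt_thin_section(5, 20, 0.04, 1.376, cfg_inv)
  expect_identical(a, b)
})

test_that("single-point inversion recovers known optical properties", {
  obs <- forward_rt_thin_section(5, 20, 0.04, 1.376, cfg_meas)
  f <- invert_rt(obs[["R"]], obs[["T"]], 0.04, 1.376, cfg_inv)
  expect_true(f$converged)
  expect_lt(abs(f$mu_a_hat - 5) / 5, 0.10)
  expect_lt(abs(f$mu_s_prime_hat - 20) / 20, 0.10)
  expect_gt(f$iterations, 0)
})

test_that("pure-absorber measurements invert to Beer-Lambert coefficients", {
  f <- invert_rt(0, exp(-2), 0.04, 1.0, cfg_inv)
  expect_lt(abs(f$mu_a_hat - 50) / 50, 0.10)
  expect_lt(f$mu_s_prime_hat, 0.5)  # at/near the lower search bound
})

test_that("a lossless slab inverts to vanishing coefficients", {
  R0 <- lossless_slab_R(1.376)
  f <- invert_rt(R0, 1 - R0, 0.04, 1.376, cfg_inv)
  expect_lt(f$mu_a_hat, 0.5)
  expect_lt(f$mu_s_prime_hat, 0.5)
  expect_true(f$at_bound)
})

test_that("infeasible measurements are rejected up front", {
  expect_error(invert_rt(0.6, 0.5, 0.04, 1.376, cfg_inv), "infeasible")
  d <- data.frame(wavelength_nm = 250, R_total = 0.7, T_total = 0.4)
  expect_error(imc_fit(d, cfg = cfg_inv), "infeasible")
})

test_that("imc_fit returns a working model object with standard methods", {
  wl <- c(250, 260, 270)
  truth <- data.frame(wavelength_nm = wl, mu_a = 5, mu_s_prime = 20, g = 0)
  d <- synth_rt_dataset(truth, noise = noise_model(0, 0, seed = 4),
                        cfg = cfg_meas)
  fit <- imc_fit(d$measurements, cfg = cfg_inv)

  expect_s3_class(fit, "imc_fit")
  expect_named(fit$coefficients,
               c("wavelength_nm", "mu_a", "mu_a_sem", "mu_s_prime",
                 "mu_s_prime_sem", "n_rep", "n_converged"))
  co <- coef(fit)
  expect_identical(dim(co), c(3L, 2L))
  expect_true(all(abs(co[, "mu_a"] - 5) / 5 < 0.10))
  expect_true(all(abs(co[, "mu_s_prime"] - 20) / 20 < 0.10))

  pr <- predict(fit)
  expect_named(pr, c("wavelength_nm", "R_pred", "T_pred"))
  expect_equal(nrow(pr), 3L)

  rs <- residuals(fit)
  expect_true(all(abs(rs$R_resid) < 0.01))
  expect_true(all(abs(rs$T_resid) < 0.01))

  ft <- fitted(fit)
  expect_true(all(c("R_fit", "T_fit") %in% names(ft)))

  expect_output(print(fit), "Inverse Monte Carlo")
  expect_output(print(summary(fit)), "converged")
  expect_silent({
    pdf(NULL)
    plot(fit)
    dev.off()
  })

  sp <- invert_spectrum(d$measurements, cfg = cfg_inv)
  expect_named(sp, c("wavelength_nm", "mu_a_per_mm", "mu_s_prime_per_mm",
                     "residual", "converged"))
  expect_equal(nrow(sp), 3L)
})

test_that("single-bin input yields a one-row coefficient table", {
  truth <- data.frame(wavelength_nm = 250, mu_a = 5, mu_s_prime = 20, g = 0)
  d <- synth_rt_dataset(truth, noise = noise_model(0, 0, seed = 4), cfg = cfg_meas)
  fit <- imc_fit(d$measurements, cfg = cfg_inv)
  expect_equal(nrow(fit$coefficients), 1L)
})

test_that("replicate scatter shrinks the standard error as k^(-1/2)", {
  # pooling after inversion: SEM of the pooled estimate scales as k^(-1/2);
  # checked on the measurement generator (sampling theory on R/T), which is
  # what drives the pooled SEM
  truth <- data.frame(wavelength_nm = c(250, 260), mu_a = 5, mu_s_prime = 20, g = 0)
  d5 <- synth_rt_dataset(truth, noise = noise_model(0.005, 0.005, seed = 6),
                         k_replicates = 5, cfg = cfg_meas)
  d20 <- synth_rt_dataset(truth, noise = noise_model(0.005, 0.005, seed = 6),
                          k_replicates = 20, cfg = cfg_meas)
  sem_k <- function(d, k) {
    x <- d$measurements
    mean(vapply(split(x$R_total, x$wavelength_nm), function(v) sd(v) / sqrt(k), 0))
  }
  # expected ratio sqrt(20/5) = 2 within sampling slack
  ratio <- sem_k(d5, 5) / sem_k(d20, 20)
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 3.5)
})
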