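#' Forward reflectance/transmittance of a thin tissue section
#'
#' Predicts total (specular + diffuse) reflectance and total transmittance
#' of a bare slab in air — the integrating-sphere geometry of a thin
#' section mounted without a substrate — by forward Monte Carlo.  The same
#' `cfg$seed` is used for every call, so the map
#' `(mu_a, mu_s_prime) -> (R, T)` is a deterministic function given the
#' configuration: the common-random-numbers device that makes the inverse
#' fit a smooth, noise-free optimization.
#'
#' @param mu_a absorption coefficient, mm^-1
#' @param mu_s_prime reduced scattering coefficient, mm^-1 (used with
#'   `g = 0` under the similarity relation unless `g` is given)
#' @param thickness section thickness, mm
#' @param n_sample section refractive index
#' @param cfg a [sim_config()]
#' @param g scattering anisotropy; the scattering coefficient passed to the
#'   kernel is `mu_s_prime / (1 - g)`
#' @return named vector `c(R = , T = )` with attribute `se` giving the
#'   Monte Carlo standard errors
#' @export
forward_rt_thin_section <- function(mu_a, mu_s_prime, thickness, n_sample,
                                    cfg, g = 0) {
  sp <- data.frame(wavelength_nm = c(100, 1000), mu_a = unname(mu_a),
                   mu_s_prime = unname(mu_s_prime), g = unname(g),
                   n = unname(n_sample))
  st <- layer_stack(list(layer("section", thickness, sp)),
                    n_above = 1, n_below = 1, boundary_mode = "fresnel")
  r <- run_forward_mc(st, 550, cfg, tally_fluence = FALSE)
  structure(c(R = r$R_specular + r$R_diffuse, T = r$T_total),
            se = c(R = r$se$R, T = r$se$T))
}

#' Search bounds and tolerances for the inverse fit
#'
#' @param mu_a_min,mu_a_max bounds on the absorption coefficient, mm^-1
#' @param mu_s_min,mu_s_max bounds on the reduced scattering coefficient
#' @param tol_rt residual (root-mean-square R/T misfit) below which a fit
#'   is declared converged
#' @param grid_n coarse log-grid resolution per parameter
#' @param maxit Nelder-Mead iteration cap
#' @return list of class `imc_control`
#' @export
imc_control <- function(mu_a_min = 1e-3, mu_a_max = 200,
                        mu_s_min = 1e-3, mu_s_max = 400,
                        tol_rt = 5e-3, grid_n = 8, maxit = 150) {
  stopifnot(mu_a_min > 0, mu_a_max > mu_a_min, mu_s_min > 0, mu_s_max > mu_s_min,
            tol_rt > 0, grid_n >= 2, maxit >= 10)
  structure(list(mu_a_min = mu_a_min, mu_a_max = mu_a_max,
                 mu_s_min = mu_s_min, mu_s_max = mu_s_max,
                 tol_rt = tol_rt, grid_n = as.integer(grid_n),
                 maxit = as.integer(maxit)),
            class = "imc_control")
}

#' Invert one reflectance/transmittance observation
#'
#' Estimates `(mu_a, mu_s_prime)` of a thin section from its measured
#' total reflectance and transmittance by matching forward Monte Carlo
#' predictions: a coarse log-spaced grid scan followed by Nelder-Mead
#' refinement in log-parameter space, all under common random numbers so
#' the objective is deterministic.
#'
#' @param RtM,TtM measured total reflectance and transmittance (fractions)
#' @param thickness section thickness, mm
#' @param n_sample section refractive index
#' @param cfg a [sim_config()] for the forward evaluations
#' @param control an [imc_control()]
#' @param start optional `c(mu_a, mu_s_prime)` warm start; skips the grid
#'   scan (used when marching along a spectrum)
#' @return list: `mu_a_hat`, `mu_s_prime_hat` (mm^-1), `residual`,
#'   `iterations`, `converged`, `at_bound`, `se_mc` (forward-model noise
#'   floor at the solution)
#' @examples
#' \donttest{
#' cfg <- sim_config(n_photons = 2e4, seed = 7)
#' obs <- forward_rt_thin_section(5, 20, 0.04, 1.376, sim_config(2e4, seed = 99))
#' fit <- invert_rt(obs["R"], obs["T"], 0.04, 1.376, cfg)
#' c(fit$mu_a_hat, fit$mu_s_prime_hat)   # near (5, 20)
#' }
#' @export
invert_rt <- function(RtM, TtM, thickness, n_sample, cfg,
                      control = imc_control(), start = NULL) {
  RtM <- as.numeric(RtM); TtM <- as.numeric(TtM)
  stopifnot_scalar(RtM, "RtM", nonneg = TRUE)
  stopifnot_scalar(TtM, "TtM", nonneg = TRUE)
  if (RtM + TtM > 1)
    stop(sprintf("infeasible measurement: RtM + TtM = %.4f > 1", RtM + TtM), call. = FALSE)
  stopifnot_scalar(thickness, "thickness", positive = TRUE)
  stopifnot(inherits(cfg, "sim_config"), inherits(control, "imc_control"))

  nev <- 0L
  fwd <- function(lp, cfg_use) {
    nev <<- nev + 1L
    p <- exp(lp)
    forward_rt_thin_section(p[1], p[2], thickness, n_sample, cfg_use)
  }
  obj_at <- function(lp, cfg_use) {
    rt <- fwd(lp, cfg_use)
    sqrt((rt[["R"]] - RtM)^2 + (rt[["T"]] - TtM)^2)
  }
  # cheap forward model for the bracketing stages, full photons for polish
  cfg_cheap <- cfg
  cfg_cheap$n_photons <- as.integer(max(1e4, cfg$n_photons / 5))

  lb <- log(c(control$mu_a_min, control$mu_s_min))
  ub <- log(c(control$mu_a_max, control$mu_s_max))

  # T is strictly decreasing in mu_a at fixed mu_s': bisection solves the
  # transmittance equation for log mu_a.
  solve_mu_a <- function(ls, cfg_use, iters = 12L) {
    lo <- lb[1]; hi <- ub[1]
    t_lo <- fwd(c(lo, ls), cfg_use)[["T"]]
    if (t_lo <= TtM) return(lo)
    t_hi <- fwd(c(hi, ls), cfg_use)[["T"]]
    if (t_hi >= TtM) return(hi)
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (fwd(c(mid, ls), cfg_use)[["T"]] > TtM) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }

  if (is.null(start)) {
    # outer bisection on log mu_s': total reflectance (with mu_a slaved to
    # the measured transmittance) increases with scattering
    r_of <- function(ls) {
      la <- solve_mu_a(ls, cfg_cheap)
      fwd(c(la, ls), cfg_cheap)[["R"]]
    }
    lo <- lb[2]; hi <- ub[2]
    if (r_of(lo) >= RtM) {
      ls0 <- lo
    } else if (r_of(hi) <= RtM) {
      ls0 <- hi
    } else {
      for (i in seq_len(11L)) {
        mid <- (lo + hi) / 2
        if (r_of(mid) < RtM) lo <- mid else hi <- mid
      }
      ls0 <- (lo + hi) / 2
    }
    p0 <- c(solve_mu_a(ls0, cfg_cheap), ls0)
    spans <- c(0.30, 0.12, 0.05)
  } else {
    p0 <- pmin(ub, pmax(lb, log(as.numeric(start))))
    spans <- c(0.40, 0.16, 0.06)
  }

  # local zooming 5x5 log-grid polish at the full photon budget; grids are
  # deterministic under the common random numbers, and a grid is robust to
  # the Monte Carlo jitter that stalls simplex methods
  best_p <- p0
  best_v <- obj_at(best_p, cfg)
  for (span in spans) {
    ga <- pmin(ub[1], pmax(lb[1], best_p[1] + seq(-span, span, length.out = 5)))
    gs <- pmin(ub[2], pmax(lb[2], best_p[2] + seq(-span, span, length.out = 5)))
    gr <- as.matrix(expand.grid(la = unique(ga), ls = unique(gs)))
    gv <- apply(gr, 1, obj_at, cfg_use = cfg)
    i <- which.min(gv)
    if (gv[i] < best_v) {
      best_p <- gr[i, ]
      best_v <- gv[i]
    }
  }
  lp <- pmin(ub, pmax(lb, best_p))
  hat <- exp(lp)
  rt <- forward_rt_thin_section(hat[1], hat[2], thickness, n_sample, cfg)
  resid <- sqrt((rt[["R"]] - RtM)^2 + (rt[["T"]] - TtM)^2)
  # "pinned at a bound" allows for the finite resolution of the final grid
  at_bound <- hat[1] <= control$mu_a_min * 3 || hat[1] >= control$mu_a_max / 3 ||
    hat[2] <= control$mu_s_min * 3 || hat[2] >= control$mu_s_max / 3
  list(mu_a_hat = hat[[1]], mu_s_prime_hat = hat[[2]], residual = resid,
       iterations = nev, converged = resid < control$tol_rt,
       at_bound = at_bound,
       se_mc = sqrt(sum(attr(rt, "se")^2)),
       R_fit = rt[["R"]], T_fit = rt[["T"]])
}

#' Fit absorption and reduced scattering spectra by inverse Monte Carlo
#'
#' The central estimator of the package.  Each row of `data` is one
#' integrating-sphere observation of a thin tissue section (total
#' reflectance and transmittance at one wavelength bin); the fit inverts
#' every row with [invert_rt()], marching through each replicate section
#' in wavelength order with warm starts, and then pools replicate
#' estimates per wavelength as mean +/- standard error of the mean.
#'
#' @param data data frame with columns `wavelength_nm`, `R_total`,
#'   `T_total`, and optionally `thickness_mm`, `n_sample`, `replicate`
#'   (defaulting to `thickness`, `n_sample`, and a single replicate)
#' @param thickness,n_sample defaults for rows lacking their own values;
#'   40 um sections (`0.04` mm) and a corneal index are typical
#' @param cfg a [sim_config()] for the forward model; the default photon
#'   count balances the Monte Carlo noise floor against runtime
#' @param control an [imc_control()]
#' @return an object of class `imc_fit` with components `coefficients`
#'   (per-wavelength pooled estimates with SEMs), `fits` (per-observation
#'   results), `data`, `cfg`, `control`, `call`.  Supported methods:
#'   [print()], [summary()], [coef()], [predict()], [fitted()],
#'   [residuals()], [plot()].
#' @examples
#' \donttest{
#' truth <- synth_optical_spectra(spectrum_params("epithelium"), seq(240, 260, 10))
#' d <- synth_rt_dataset(truth, cfg = sim_config(2e4, seed = 5),
#'                       noise = noise_model(0, 0, seed = 1))
#' fit <- imc_fit(d$measurements, cfg = sim_config(2e4, seed = 11))
#' coef(fit)
#' }
#' @export
imc_fit <- function(data, thickness = 0.04, n_sample = 1.376,
                    cfg = sim_config(n_photons = 5e4, seed = 1),
                    control = imc_control()) {
  cl <- match.call()
  data <- as.data.frame(data)
  need <- c("wavelength_nm", "R_total", "T_total")
  missing <- setdiff(need, names(data))
  if (length(missing))
    stop("'data' is missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(data$thickness_mm)) data$thickness_mm <- thickness
  if (is.null(data$n_sample)) data$n_sample <- n_sample
  if (is.null(data$replicate)) data$replicate <- 1L
  bad <- which(data$R_total + data$T_total > 1)
  if (length(bad))
    stop("infeasible measurement (R + T > 1) at row ", bad[1], call. = FALSE)

  data <- data[order(data$replicate, data$wavelength_nm), , drop = FALSE]
  rownames(data) <- NULL

  fits <- vector("list", nrow(data))
  for (rep_id in unique(data$replicate)) {
    idx <- which(data$replicate == rep_id)
    start <- NULL
    for (i in idx) {
      f <- invert_rt(data$R_total[i], data$T_total[i], data$thickness_mm[i],
                     data$n_sample[i], cfg, control, start = start)
      # a poor warm-started fit falls back to the full grid scan
      if (!is.null(start) && !f$converged && f$residual > 4 * control$tol_rt) {
        f2 <- invert_rt(data$R_total[i], data$T_total[i], data$thickness_mm[i],
                        data$n_sample[i], cfg, control, start = NULL)
        if (f2$residual < f$residual) f <- f2
      }
      fits[[i]] <- f
      start <- if (f$converged) c(f$mu_a_hat, f$mu_s_prime_hat) else NULL
    }
  }
  fits_df <- cbind(
    data[, c("wavelength_nm", "replicate")],
    do.call(rbind, lapply(fits, function(f)
      data.frame(mu_a_hat = f$mu_a_hat, mu_s_prime_hat = f$mu_s_prime_hat,
                 residual = f$residual, iterations = f$iterations,
                 converged = f$converged, at_bound = f$at_bound,
                 se_mc = f$se_mc, R_fit = f$R_fit, T_fit = f$T_fit))))

  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  agg <- do.call(rbind, lapply(split(fits_df, fits_df$wavelength_nm), function(d) {
    ok <- d$converged
    use <- if (any(ok)) d[ok, , drop = FALSE] else d
    data.frame(wavelength_nm = d$wavelength_nm[1],
               mu_a = mean(use$mu_a_hat), mu_a_sem = sem(use$mu_a_hat),
               mu_s_prime = mean(use$mu_s_prime_hat),
               mu_s_prime_sem = sem(use$mu_s_prime_hat),
               n_rep = nrow(d), n_converged = sum(ok))
  }))
  agg <- agg[order(agg$wavelength_nm), , drop = FALSE]
  rownames(agg) <- NULL

  structure(list(coefficients = agg, fits = fits_df, data = data,
                 cfg = cfg, control = control, call = cl),
            class = "imc_fit")
}

#' Invert a whole reflectance/transmittance spectrum
#'
#' Convenience wrapper around [imc_fit()] returning the per-wavelength
#' coefficient table in the on-disk result format.
#'
#' @inheritParams imc_fit
#' @return data frame `wavelength_nm`, `mu_a_per_mm`, `mu_s_prime_per_mm`,
#'   `residual`, `converged`
#' @export
invert_spectrum <- function(data, thickness = 0.04, n_sample = 1.376,
                            cfg = sim_config(n_photons = 5e4, seed = 1),
                            control = imc_control()) {
  fit <- imc_fit(data, thickness, n_sample, cfg, control)
  res <- do.call(rbind, lapply(split(fit$fits, fit$fits$wavelength_nm), function(d)
    data.frame(wavelength_nm = d$wavelength_nm[1],
               residual = mean(d$residual), converged = all(d$converged))))
  out <- merge(fit$coefficients[, c("wavelength_nm", "mu_a", "mu_s_prime")],
               res, by = "wavelength_nm")
  names(out)[names(out) == "mu_a"] <- "mu_a_per_mm"
  names(out)[names(out) == "mu_s_prime"] <- "mu_s_prime_per_mm"
  out[order(out$wavelength_nm), , drop = FALSE]
}

#' @export
print.imc_fit <- function(x, ...) {
  cat("Inverse Monte Carlo fit of thin-section optical properties\n")
  cat(sprintf("  %d observation(s), %d wavelength bin(s), %d replicate(s)\n",
              nrow(x$fits), nrow(x$coefficients), length(unique(x$fits$replicate))))
  cat(sprintf("  converged: %d/%d (tol_rt = %g)\n",
              sum(x$fits$converged), nrow(x$fits), x$control$tol_rt))
  cat(sprintf("  mu_a:  %.3g - %.3g mm^-1 | mu_s': %.3g - %.3g mm^-1\n",
              min(x$coefficients$mu_a), max(x$coefficients$mu_a),
              min(x$coefficients$mu_s_prime), max(x$coefficients$mu_s_prime)))
  invisible(x)
}

#' @export
summary.imc_fit <- function(object, ...) {
  structure(list(coefficients = object$coefficients,
                 n_obs = nrow(object$fits),
                 n_converged = sum(object$fits$converged),
                 n_at_bound = sum(object$fits$at_bound),
                 median_residual = median(object$fits$residual),
                 max_residual = max(object$fits$residual),
                 tol_rt = object$control$tol_rt,
                 call = object$call),
            class = "summary.imc_fit")
}

#' @export
print.summary.imc_fit <- function(x, ...) {
  cat("Call: "); print(x$call)
  cat(sprintf("\n%d observations: %d converged, %d at a search bound\n",
              x$n_obs, x$n_converged, x$n_at_bound))
  cat(sprintf("residual (RMS of R/T misfit): median %.2e, max %.2e (tol %.0e)\n\n",
              x$median_residual, x$max_residual, x$tol_rt))
  print(x$coefficients, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.imc_fit <- function(object, ...) {
  m <- as.matrix(object$coefficients[, c("mu_a", "mu_s_prime")])
  rownames(m) <- object$coefficients$wavelength_nm
  m
}

#' Predict reflectance/transmittance from a fitted inverse model
#'
#' Evaluates the forward Monte Carlo model at the pooled per-wavelength
#' coefficient estimates.
#'
#' @param object an [imc_fit()] object
#' @param newdata optional data frame with `wavelength_nm` (a subset of the
#'   fitted bins) and optionally `thickness_mm`, `n_sample`; defaults to
#'   the fitted bins at the fit's median geometry
#' @param ... unused
#' @return data frame `wavelength_nm`, `R_pred`, `T_pred`
#' @export
predict.imc_fit <- function(object, newdata = NULL, ...) {
  co <- object$coefficients
  if (is.null(newdata)) {
    newdata <- data.frame(wavelength_nm = co$wavelength_nm,
                          thickness_mm = median(object$data$thickness_mm),
                          n_sample = median(object$data$n_sample))
  }
  newdata <- as.data.frame(newdata)
  if (is.null(newdata$thickness_mm)) newdata$thickness_mm <- median(object$data$thickness_mm)
  if (is.null(newdata$n_sample)) newdata$n_sample <- median(object$data$n_sample)
  idx <- match(newdata$wavelength_nm, co$wavelength_nm)
  if (anyNA(idx))
    stop("predict() only evaluates at fitted wavelength bins", call. = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(newdata)), function(i) {
    rt <- forward_rt_thin_section(co$mu_a[idx[i]], co$mu_s_prime[idx[i]],
                                  newdata$thickness_mm[i], newdata$n_sample[i],
                                  object$cfg)
    data.frame(wavelength_nm = newdata$wavelength_nm[i],
               R_pred = rt[["R"]], T_pred = rt[["T"]])
  }))
  rownames(out) <- NULL
  out
}

#' @export
fitted.imc_fit <- function(object, ...) {
  object$fits[, c("wavelength_nm", "replicate", "R_fit", "T_fit")]
}

#' Residual reflectance/transmittance misfit of an inverse fit
#'
#' @param object an [imc_fit()] object
#' @param ... unused
#' @return data frame of per-observation residuals `R_resid = R_total -
#'   R_fit` and `T_resid = T_total - T_fit`
#' @export
residuals.imc_fit <- function(object, ...) {
  data.frame(wavelength_nm = object$fits$wavelength_nm,
             replicate = object$fits$replicate,
             R_resid = object$data$R_total - object$fits$R_fit,
             T_resid = object$data$T_total - object$fits$T_fit)
}

#' Plot fitted optical-property spectra
#'
#' @param x an [imc_fit()] object
#' @param ... passed to [plot()]
#' @export
plot.imc_fit <- function(x, ...) {
  co <- x$coefficients
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (p in c("mu_a", "mu_s_prime")) {
    v <- co[[p]]; s <- co[[paste0(p, "_sem")]]
    ylim <- range(c(v - s, v + s, v), na.rm = TRUE)
    plot(co$wavelength_nm, v, type = "b", pch = 19, ylim = ylim,
         xlab = "wavelength (nm)",
         ylab = if (p == "mu_a") expression(mu[a] ~ (mm^-1)) else expression(mu[s] * "'" ~ (mm^-1)),
         ...)
    ok <- !is.na(s) & s > 0
    if (any(ok))
      arrows(co$wavelength_nm[ok], (v - s)[ok], co$wavelength_nm[ok], (v + s)[ok],
             angle = 90, code = 3, length = 0.03)
  }
  invisible(x)
}
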