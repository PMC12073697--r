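# Synthetic generators: determinism, physical structure, and closure of
# the generate -> analyse round trips.

test_that("generators are pure functions of scenario and seed", {
  sc <- dielectric_scenario(seed = 5, noise_rel_sd = 0.02)
  s1 <- gen_spectrum(sc, 100)
  s2 <- gen_spectrum(sc, 100)
  expect_identical(s1, s2)
  # different temperature draws different noise
  s3 <- gen_spectrum(sc, 105)
  expect_false(identical(s1$eps_real, s3$eps_real))
  ts <- thermo_scenario(seed = 5)
  expect_identical(gen_thermogram(ts), gen_thermogram(ts))
  refs <- vtfh_reference_set(c(0.49, 0.70, 0.90, 1.0))
  r1 <- gen_recrystallization_series(sc, 0:3, c(0.9, 0.8, 0.75, 0.72),
                                     90, refs)
  r2 <- gen_recrystallization_series(sc, 0:3, c(0.9, 0.8, 0.75, 0.72),
                                     90, refs)
  expect_identical(r1, r2)
})

test_that("an empty scenario is a flat spectrum", {
  sc <- dielectric_scenario(modes = list(), eps_inf = 4, c_cond = 0,
                            noise_rel_sd = 0)
  sp <- gen_spectrum(sc, 100)
  expect_true(all(sp$eps_real == 4))
  expect_true(all(sp$eps_imag == 0))
})

test_that("the ohmic term separates exactly from the generated loss", {
  base <- dielectric_scenario(seed = 3, c_cond = 0, noise_rel_sd = 0.01,
                              ep_amplitude = 0.5)
  with_cond <- dielectric_scenario(seed = 3, c_cond = 2,
                                   noise_rel_sd = 0.01, ep_amplitude = 0.5)
  s0 <- gen_spectrum(base, 100)
  s1 <- gen_spectrum(with_cond, 100)
  expect_equal(s1$eps_imag - s0$eps_imag,
               2 / (2 * pi * s1$frequencies), tolerance = 1e-14)
  expect_identical(s1$eps_real, s0$eps_real)
})

test_that("a generated Debye mode closes the fit round trip within 1%", {
  sc <- dielectric_scenario(
    modes = list(list(vtfh = vtfh_params(B = 2000, t0 = 0),
                      delta_eps = 2, d_delta_eps_dT = 0,
                      alpha = 1, beta = 1)),
    eps_inf = 3, c_cond = 0, noise_rel_sd = 0)
  sp <- gen_spectrum(sc, 100)
  fit <- fit_hn(sp, 1, "eps_imag")
  tau_truth <- 10^vtfh_eval(vtfh_params(B = 2000, t0 = 0), 100)
  expect_equal(fit$modes[[1]]$tau_hn, tau_truth, tolerance = 0.01)
  expect_equal(fit$modes[[1]]$delta_eps, 2, tolerance = 0.01)
  expect_equal(fit$eps_inf, 3, tolerance = 0.01)
  # domain error below the Vogel temperature
  expect_error(gen_spectrum(sc, -5), "Vogel")
})

test_that("isotherm series move their loss peaks to higher frequency with T", {
  sc <- dielectric_scenario(noise_rel_sd = 0,
                            temperatures = seq(85, 110, 5))
  series <- gen_isotherm_series(sc)
  peak_f <- vapply(series, function(sp) {
    sp <- log_derivative(sp)
    sp$frequencies[which.max(sp$eps_der)]
  }, numeric(1))
  expect_true(all(diff(peak_f) > 0))
  expect_error(gen_isotherm_series(
    dielectric_scenario(temperatures = 100)), "at least 2")
})

test_that("the derive-fit-VTFH pipeline closes on a noiseless two-mode series", {
  # two components patterned on the 90 wt.% dispersion, analysed over the
  # span where both stay inside the sweep window
  sc <- dielectric_scenario(noise_rel_sd = 0, c_cond = 0.2,
                            temperatures = seq(85, 110, 5))
  series <- gen_isotherm_series(sc)
  pts <- do.call(rbind, lapply(series, function(sp) {
    fit <- fit_hn(log_derivative(sp), 2, "eps_der")
    rbind(hn_peak_tau(fit, 1), hn_peak_tau(fit, 2))
  }))
  truth <- list(alpha1 = c(B = 2356, t0K = 275.15),
                alpha2 = c(B = 1759, t0K = 284.35))
  for (lbl in names(truth)) {
    v <- fit_vtfh(pts[pts$label == lbl, ])
    expect_equal(v$B, unname(truth[[lbl]]["B"]), tolerance = 0.05)
    expect_equal(v$t0 + 273.15, unname(truth[[lbl]]["t0K"]),
                 tolerance = 0.05)
  }
})

test_that("1% multiplicative noise degrades the recovery to within 10%", {
  sc <- dielectric_scenario(seed = 1, noise_rel_sd = 0.01, c_cond = 0.2,
                            temperatures = seq(80, 110, 5))
  series <- gen_isotherm_series(sc)
  warm <- NULL
  pts <- NULL
  for (sp in series) {
    sp <- log_derivative(sp, smoothing_window = 7, points_per_decade = 10)
    fit <- suppressWarnings(fit_hn(sp, 2, "eps_der", start = warm))
    warm <- fit
    if (!fit$at_bounds)
      pts <- rbind(pts, rbind(hn_peak_tau(fit, 1), hn_peak_tau(fit, 2)))
  }
  truth <- list(alpha1 = c(B = 2356, t0K = 275.15),
                alpha2 = c(B = 1759, t0K = 284.35))
  for (lbl in names(truth)) {
    v <- fit_vtfh(pts[pts$label == lbl, ])
    expect_equal(v$B, unname(truth[[lbl]]["B"]), tolerance = 0.10)
    expect_equal(v$t0 + 273.15, unname(truth[[lbl]]["t0K"]),
                 tolerance = 0.10)
  }
})

test_that("thermogram peaks integrate to their stated enthalpy", {
  ts <- thermo_scenario(seed = 5, noise_sd = 0, baseline_slope = 0,
                        transitions = list(),
                        peaks = list(list(center = 120, enthalpy = 52,
                                          width = 4, sign = -1)))
  tg <- gen_thermogram(ts)
  area <- -sum(tg$rev_cp - ts$baseline_level) * ts$t_step
  expect_equal(area, 52, tolerance = 0.5 / 52)
  expect_error(thermo_scenario(transitions = list(
    list(tg_mid = 80, delta_cp = 0.4, width = 3),
    list(tg_mid = 83, delta_cp = 0.4, width = 3))), "overlapping")
})

test_that("recrystallisation series are tracked back to the final composition", {
  refs <- vtfh_reference_set(c(0.49, 0.70, 0.90, 1.0))
  sc <- dielectric_scenario(noise_rel_sd = 0, c_cond = 0.2, seed = 1)
  times <- seq(0, 8, length.out = 9)
  x2 <- 0.65 + (0.90 - 0.65) * exp(-times / 1.5)
  series <- gen_recrystallization_series(sc, times, x2, 90, refs,
                                         x1 = 0.60)
  tab <- suppressWarnings(
    track_recrystallization(series, times, references = refs))
  expect_true(attr(tab, "delta_eps_a2_monotone"))
  expect_equal(tab$x_est[nrow(tab)], x2[length(x2)], tolerance = 0.05 / 0.65)
  expect_gte(tab$x_est[nrow(tab)], 0.60)
  expect_lte(tab$x_est[nrow(tab)], 0.70)
  # non-monotone composition paths are rejected
  expect_error(gen_recrystallization_series(sc, 0:3,
                                            c(0.9, 0.8, 0.85, 0.8),
                                            90, refs), "monotone")
})

test_that("a static series tracks flat", {
  refs <- vtfh_reference_set(c(0.49, 0.70, 0.90, 1.0))
  sc <- dielectric_scenario(noise_rel_sd = 0, c_cond = 0.2, seed = 2)
  series <- gen_recrystallization_series(sc, 0:4, rep(0.8, 5), 90, refs,
                                         x1 = 0.60)
  tab <- suppressWarnings(
    track_recrystallization(series, 0:4, references = refs))
  expect_lt(diff(range(tab$log10_tau_a2)), 1e-8)
  expect_lt(diff(range(tab$delta_eps_a2)), 1e-8)
  expect_lt(diff(range(tab$x_est)), 1e-8)
})

test_that("a series collapsing to one mode degrades gracefully", {
  refs <- vtfh_reference_set(c(0.49, 0.70, 0.90, 1.0))
  sc <- dielectric_scenario(noise_rel_sd = 0, c_cond = 0, seed = 3)
  # alpha2 strength decays to the 1e-6 floor: effectively one mode left
  times <- 0:4
  x2 <- c(0.90, 0.75, 0.68, 0.655, 0.6501)
  series <- gen_recrystallization_series(sc, times, x2, 90, refs,
                                         x1 = 0.65)
  tab <- suppressWarnings(
    track_recrystallization(series, times, references = refs))
  expect_equal(nrow(tab), 5L)
  expect_true(all(tab$n_modes_used %in% c(1L, 2L)))
  expect_true(all(is.finite(tab$log10_tau_a2)))
})
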