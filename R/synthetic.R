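#' Synthetic dielectric measurement scenario
#'
#' Ground-truthed forward model of a broadband dielectric measurement on a
#' supercooled drug/polymer dispersion: one or two HN relaxation modes
#' whose relaxation times follow per-mode VTFH laws, plus ohmic
#' conductivity (eps''_cond = c_cond / omega), low-frequency electrode
#' polarisation modelled as a power law a (i omega)^(-s), and
#' multiplicative measurement noise.  The relaxation strength of each mode
#' varies affinely with temperature about 110 degC.
#'
#' The default scenario mirrors the dispersion with 90 wt.% drug: a
#' minority low-frequency component (alpha1, VTFH B = 2356 K,
#' T0 = 2.0 degC) and a majority high-frequency component (alpha2,
#' B = 1759 K, T0 = 11.2 degC) with a 1:4 strength ratio, swept from
#' 0.1 Hz to 1 MHz at 10 points per decade over 85-150 degC isotherms.
#'
#' @param seed integer; the scenario is a pure function of (scenario,
#'   seed).
#' @param freq_min,freq_max sweep limits, Hz.
#' @param points_per_decade sweep density.
#' @param temperatures isotherm list, degC.
#' @param modes list of mode descriptions, each a list with `vtfh` (a
#'   [vtfh_params()]), `delta_eps` (strength at 110 degC), `d_delta_eps_dT`
#'   (affine slope per degC), `alpha`, `beta`.
#' @param eps_inf high-frequency permittivity.
#' @param c_cond ohmic amplitude: eps''_cond = c_cond / omega (rad/s).
#' @param ep_amplitude,ep_exponent electrode polarisation a and s
#'   (0 < s < 1).
#' @param noise_rel_sd relative (multiplicative) noise standard deviation.
#' @return An object of class `dielectric_scenario`.
#' @export
dielectric_scenario <- function(seed = 1L,
                                freq_min = 0.1, freq_max = 1e6,
                                points_per_decade = 10L,
                                temperatures = seq(85, 150, by = 5),
                                modes = list(
                                  list(vtfh = vtfh_params(B = 2356, t0 = 2.0),
                                       delta_eps = 0.75,
                                       d_delta_eps_dT = 0,
                                       alpha = 0.85, beta = 0.7),
                                  list(vtfh = vtfh_params(B = 1759, t0 = 11.2),
                                       delta_eps = 3,
                                       d_delta_eps_dT = 0,
                                       alpha = 0.85, beta = 0.7)),
                                eps_inf = 3,
                                c_cond = 0.5,
                                ep_amplitude = 0, ep_exponent = 0.8,
                                noise_rel_sd = 0.01) {
  if (ep_amplitude < 0 || c_cond < 0 || noise_rel_sd < 0)
    stop("amplitudes must be >= 0")
  if (ep_amplitude > 0 && (ep_exponent <= 0 || ep_exponent >= 1))
    stop("ep_exponent must be in (0, 1)")
  for (m in modes) stopifnot(inherits(m$vtfh, "vtfh_params"))
  structure(list(seed = as.integer(seed), freq_min = freq_min,
                 freq_max = freq_max,
                 points_per_decade = as.integer(points_per_decade),
                 temperatures = temperatures, modes = modes,
                 eps_inf = eps_inf, c_cond = c_cond,
                 ep_amplitude = ep_amplitude, ep_exponent = ep_exponent,
                 noise_rel_sd = noise_rel_sd),
            class = "dielectric_scenario")
}

scenario_frequencies <- function(sc) {
  10^seq(log10(sc$freq_min), log10(sc$freq_max),
         by = 1 / sc$points_per_decade)
}

scenario_modes_at <- function(sc, temperature, t_ref = 110) {
  lapply(sc$modes, function(m) {
    tau <- 10^vtfh_eval(m$vtfh, temperature)
    de <- m$delta_eps + m$d_delta_eps_dT * (temperature - t_ref)
    if (de <= 0) stop("mode strength non-positive at ", temperature, " degC")
    hn_mode(de, tau, m$alpha, m$beta)
  })
}

#' Generate one synthetic isotherm spectrum
#'
#' Evaluates the scenario's forward model at one temperature: HN modes
#' (with tau from each mode's VTFH law) plus electrode polarisation split
#' into its standard real/imaginary parts, multiplicative noise on the
#' relaxation signal, and finally the ohmic term c_cond/omega added to
#' the loss.  Noise is seeded deterministically from the scenario seed
#' and the temperature, so identical calls are bit-identical.
#'
#' @param scenario a [dielectric_scenario()].
#' @param temperature degC; must exceed every mode's Vogel temperature.
#' @return A [dielectric_spectrum()].
#' @export
gen_spectrum <- function(scenario, temperature) {
  stopifnot(inherits(scenario, "dielectric_scenario"))
  f <- scenario_frequencies(scenario)
  w <- 2 * pi * f
  modes <- scenario_modes_at(scenario, temperature)  # errors if T <= T0
  ev <- hn_eval(scenario$eps_inf, modes, f)
  er <- ev$eps_real
  ei <- ev$eps_imag
  if (scenario$ep_amplitude > 0) {
    s <- scenario$ep_exponent
    er <- er + scenario$ep_amplitude * w^(-s) * cos(pi * s / 2)
    ei <- ei + scenario$ep_amplitude * w^(-s) * sin(pi * s / 2)
  }
  if (scenario$noise_rel_sd > 0) {
    local_seed <- (scenario$seed + round(100 * temperature)) %% .Machine$integer.max
    withr::with_seed(local_seed, {
      er <- er * (1 + stats::rnorm(length(f), sd = scenario$noise_rel_sd))
      ei <- ei * (1 + stats::rnorm(length(f), sd = scenario$noise_rel_sd))
    })
  }
  # ohmic conduction enters the loss after the noise so that subtracting a
  # c_cond = 0 twin recovers c_cond/omega exactly
  ei <- ei + scenario$c_cond / w
  dielectric_spectrum(temperature, f, er, ei)
}

#' Generate a temperature series of isotherm spectra
#'
#' @param scenario a [dielectric_scenario()] with >= 2 temperatures.
#' @return List of [dielectric_spectrum()], one per scenario temperature;
#'   the loss-peak frequency increases with temperature.
#' @export
gen_isotherm_series <- function(scenario) {
  stopifnot(inherits(scenario, "dielectric_scenario"))
  if (length(scenario$temperatures) < 2L)
    stop("an isotherm series needs at least 2 temperatures")
  lapply(scenario$temperatures, function(tc) gen_spectrum(scenario, tc))
}

#' Synthetic thermogram scenario
#'
#' Forward model of a reversible-heat-capacity scan: an affine baseline,
#' one or more logistic Cp steps (glass transitions; the slope at the
#' midpoint is delta_cp/(4 width)), optional Gaussian exo/endothermic
#' peaks with a stated integrated enthalpy, and additive noise.
#'
#' @param seed integer RNG seed.
#' @param t_min,t_max,t_step temperature scan, degC.
#' @param baseline_level Cp baseline at `t_min`, J g^-1 degC^-1.
#' @param baseline_slope baseline slope, J g^-1 degC^-2.
#' @param transitions list of `list(tg_mid, delta_cp, width)` (widths in
#'   degC, > 0, non-overlapping).
#' @param peaks list of `list(center, enthalpy, width, sign)` with
#'   enthalpy in J g^-1 (integrated area) and sign +1 (endotherm) or -1
#'   (exotherm).
#' @param noise_sd additive noise, J g^-1 degC^-1.
#' @return An object of class `thermo_scenario`.
#' @export
thermo_scenario <- function(seed = 1L, t_min = 20, t_max = 160,
                            t_step = 0.1,
                            baseline_level = 1.2, baseline_slope = 0.001,
                            transitions = list(
                              list(tg_mid = 81, delta_cp = 0.45, width = 3)),
                            peaks = list(),
                            noise_sd = 0.002) {
  for (tr in transitions)
    if (tr$width <= 0) stop("transition widths must be > 0")
  if (length(transitions) > 1L) {
    mids <- vapply(transitions, `[[`, numeric(1), "tg_mid")
    wids <- vapply(transitions, `[[`, numeric(1), "width")
    o <- order(mids)
    mids <- mids[o]; wids <- wids[o]
    if (any(diff(mids) < 6 * (utils::head(wids, -1) + wids[-1])))
      stop("scenario error: overlapping glass transitions")
  }
  for (p in peaks) if (p$width <= 0) stop("peak widths must be > 0")
  structure(list(seed = as.integer(seed), t_min = t_min, t_max = t_max,
                 t_step = t_step, baseline_level = baseline_level,
                 baseline_slope = baseline_slope,
                 transitions = transitions, peaks = peaks,
                 noise_sd = noise_sd),
            class = "thermo_scenario")
}

#' Generate a synthetic thermogram
#'
#' @param scenario a [thermo_scenario()].
#' @return A [thermogram()]; each Gaussian peak integrates to its stated
#'   enthalpy and each logistic step to its stated Cp-jump.
#' @export
gen_thermogram <- function(scenario) {
  stopifnot(inherits(scenario, "thermo_scenario"))
  tt <- seq(scenario$t_min, scenario$t_max, by = scenario$t_step)
  cp <- scenario$baseline_level +
    scenario$baseline_slope * (tt - scenario$t_min)
  for (tr in scenario$transitions)
    cp <- cp + tr$delta_cp / (1 + exp(-(tt - tr$tg_mid) / tr$width))
  for (p in scenario$peaks)
    cp <- cp + p$sign * p$enthalpy *
      stats::dnorm(tt, mean = p$center, sd = p$width)
  if (scenario$noise_sd > 0)
    withr::with_seed(scenario$seed, {
      cp <- cp + stats::rnorm(length(tt), sd = scenario$noise_sd)
    })
  thermogram(tt, cp)
}

#' Generate an isothermal recrystallisation spectral series
#'
#' Emulates repeated dielectric sweeps during isothermal
#' recrystallisation of a supersaturated dispersion held at fixed
#' temperature.  The composition of the drug-rich (alpha2) amorphous
#' phase follows `x2_path` over time; its relaxation time is interpolated
#' at that composition across the reference VTFH curves (the same
#' interpolation [estimate_composition()] inverts), and its strength is
#' scaled by the fraction of the drug load still amorphous implied by
#' mass balance from the initial composition.  The minority alpha1 phase
#' keeps the composition `x1` throughout.
#'
#' @param scenario a [dielectric_scenario()] providing the grid, shapes,
#'   conduction/EP/noise; its first and second mode templates are used for
#'   alpha1 and alpha2.
#' @param times numeric time stamps (>= 3).
#' @param x2_path numeric vector, drug weight fraction of the alpha2
#'   phase at each time; monotone non-increasing.
#' @param temperature degC of the isotherm.
#' @param references named list of [vtfh_params()] keyed by composition
#'   (see [vtfh_reference_set()]).
#' @param x1 fixed composition of the alpha1 phase (default: final
#'   `x2_path` value).
#' @return List of [dielectric_spectrum()] of length `length(times)`.
#' @export
gen_recrystallization_series <- function(scenario, times, x2_path,
                                         temperature, references,
                                         x1 = NULL) {
  stopifnot(inherits(scenario, "dielectric_scenario"))
  if (length(times) < 3L) stop("need at least 3 time points")
  stopifnot(length(x2_path) == length(times))
  if (any(diff(x2_path) > 1e-12))
    stop("scenario error: x2_path must be monotone non-increasing")
  if (is.null(x1)) x1 <- x2_path[length(x2_path)]
  xs <- as.numeric(names(references))
  ord <- order(xs)
  xs <- xs[ord]; references <- references[ord]
  lt_refs <- vapply(references, vtfh_eval, numeric(1),
                    temperature = temperature)
  log_tau_at <- function(x)
    stats::approx(xs, lt_refs, xout = x, rule = 2)$y
  x0 <- x2_path[1]
  f <- scenario_frequencies(scenario)
  w <- 2 * pi * f
  m1t <- scenario$modes[[1]]
  m2t <- scenario$modes[[min(2L, length(scenario$modes))]]
  out <- vector("list", length(times))
  for (i in seq_along(times)) {
    x2 <- x2_path[i]
    # amorphous drug fraction from mass balance relative to the start
    f_am <- if (x2 >= x0) 1 else x2 * (1 - x0) / (x0 * (1 - x2))
    modes <- list(
      hn_mode(m1t$delta_eps, 10^log_tau_at(x1), m1t$alpha, m1t$beta),
      hn_mode(max(m2t$delta_eps * f_am, 1e-6), 10^log_tau_at(x2),
              m2t$alpha, m2t$beta))
    ev <- hn_eval(scenario$eps_inf, modes, f)
    er <- ev$eps_real; ei <- ev$eps_imag
    if (scenario$ep_amplitude > 0) {
      s <- scenario$ep_exponent
      er <- er + scenario$ep_amplitude * w^(-s) * cos(pi * s / 2)
      ei <- ei + scenario$ep_amplitude * w^(-s) * sin(pi * s / 2)
    }
    if (scenario$noise_rel_sd > 0) {
      local_seed <- (scenario$seed + 7919L * i) %% .Machine$integer.max
      withr::with_seed(local_seed, {
        er <- er * (1 + stats::rnorm(length(f), sd = scenario$noise_rel_sd))
        ei <- ei * (1 + stats::rnorm(length(f), sd = scenario$noise_rel_sd))
      })
    }
    ei <- ei + scenario$c_cond / w
    out[[i]] <- dielectric_spectrum(temperature, f, er, ei)
  }
  out
}
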