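#' Havriliak-Negami relaxation mode
#'
#' One empirical relaxation mode
#' eps*(omega) = eps_inf + delta_eps / (1 + (i omega tau_HN)^alpha_HN)^beta_HN
#' with broadening exponent alpha_HN and asymmetry exponent beta_HN, both in
#' (0, 1]; alpha = beta = 1 recovers the Debye case.
#'
#' @param delta_eps relaxation strength, > 0.
#' @param tau_hn characteristic HN time, seconds, > 0.
#' @param alpha_hn,beta_hn shape exponents in (0, 1].
#' @return An object of class `hn_mode`.
#' @export
hn_mode <- function(delta_eps, tau_hn, alpha_hn = 1, beta_hn = 1) {
  if (!is.finite(delta_eps) || delta_eps <= 0) stop("delta_eps must be > 0")
  if (!is.finite(tau_hn) || tau_hn <= 0) stop("tau_hn must be > 0")
  if (alpha_hn <= 0 || alpha_hn > 1) stop("alpha_hn must be in (0, 1]")
  if (beta_hn <= 0 || beta_hn > 1) stop("beta_hn must be in (0, 1]")
  structure(list(delta_eps = delta_eps, tau_hn = tau_hn,
                 alpha_hn = alpha_hn, beta_hn = beta_hn),
            class = "hn_mode")
}

#' Evaluate a sum of Havriliak-Negami modes
#'
#' Evaluates eps* = eps_inf + sum of HN modes at the given frequencies and
#' returns the convention eps* = eps' - i eps'' as two real arrays.
#' Contributions of multiple modes add; a single mode gives an eps'
#' monotonically non-increasing with frequency and eps'' >= 0.
#'
#' @param eps_inf high-frequency permittivity limit, >= 0.
#' @param modes list of [hn_mode()] objects (possibly empty if `eps_inf`
#'   is given).
#' @param frequencies Hz, > 0.
#' @return list with `eps_real` and `eps_imag`.
#' @examples
#' hn_eval(3, list(hn_mode(2, 1 / (2 * pi))), 1)  # Debye at omega*tau = 1
#' @export
hn_eval <- function(eps_inf, modes, frequencies) {
  if (length(modes) == 0 && (is.null(eps_inf) || !is.finite(eps_inf)))
    stop("invalid model: no modes and no eps_inf")
  if (any(frequencies <= 0)) stop("frequencies must be > 0")
  w <- 2 * pi * frequencies
  es <- rep(complex(real = eps_inf), length(w))
  for (m in modes) {
    stopifnot(inherits(m, "hn_mode"))
    a <- (1 + (1i * w * m$tau_hn)^m$alpha_hn)^(-m$beta_hn)
    es <- es + m$delta_eps * a
  }
  list(eps_real = Re(es), eps_imag = -Im(es))
}

#' Analytic conduction-free loss of an HN model
#'
#' The model curve commensurate with [log_derivative()] data:
#' eps''_der = -(pi/2) d eps'_model / d ln omega evaluated in closed form,
#' mode by mode, as (pi/2) alpha beta delta_eps Re(u (1+u)^(-beta-1)) with
#' u = (i omega tau)^alpha.
#'
#' @inheritParams hn_eval
#' @return numeric vector, the model eps''_der at `frequencies`.
#' @export
hn_deriv_loss <- function(modes, frequencies) {
  w <- 2 * pi * frequencies
  out <- numeric(length(w))
  for (m in modes) {
    u <- (1i * w * m$tau_hn)^m$alpha_hn
    out <- out + (pi / 2) * m$alpha_hn * m$beta_hn * m$delta_eps *
      Re(u * (1 + u)^(-m$beta_hn - 1))
  }
  out
}

#' Peak relaxation time of an HN mode
#'
#' The loss peak of an HN mode lies at
#' omega_max = tau_HN^-1 * (sin(pi alpha/(2(beta+1))) /
#'                          sin(pi alpha beta/(2(beta+1))))^(1/alpha),
#' which reduces to 1/tau_HN in the Debye case.  Returns the corresponding
#' relaxation point with tau_max = 1/omega_max.
#'
#' @param fit an [hn_fit] object (from [fit_hn()]) or a list of
#'   [hn_mode()]s wrapped in `list(modes = ...)`.
#' @param mode_index which mode (1 = longer-tau / low-frequency component).
#' @param temperature degC to record (defaults to the fit's temperature).
#' @return A [relaxation_point()] labelled `alpha` for a one-mode fit,
#'   `alpha1`/`alpha2` for the longer/shorter tau mode of a two-mode fit.
#' @export
hn_peak_tau <- function(fit, mode_index = 1L, temperature = NULL) {
  modes <- fit$modes
  if (mode_index < 1L || mode_index > length(modes))
    stop("mode_index out of range")
  m <- modes[[mode_index]]
  om <- hn_omega_max(m)
  if (is.null(temperature)) temperature <- fit$temperature
  if (is.null(temperature)) temperature <- NA_real_
  lbl <- if (length(modes) == 1L) "alpha"
         else if (mode_index == 1L) "alpha1" else "alpha2"
  relaxation_point(temperature, -log10(om), label = lbl, method = "hn-fit")
}

hn_omega_max <- function(m) {
  a <- m$alpha_hn; b <- m$beta_hn
  (1 / m$tau_hn) *
    (sin(pi * a / (2 * (b + 1))) / sin(pi * a * b / (2 * (b + 1))))^(1 / a)
}

#' Fit Havriliak-Negami modes to a loss spectrum
#'
#' Deconvolutes a dielectric loss curve into one or two HN modes by
#' bounded Levenberg-Marquardt least squares.  The fit target is either
#' the conduction-free derivative loss (`"eps_der"`, fitted with the
#' analytic [hn_deriv_loss()] model so model and data are commensurate) or
#' the raw imaginary part (`"eps_imag"`).  The low-frequency electrode
#' polarisation rise is not modelled: restrict `freq_window` to exclude
#' it.
#'
#' Initial values are seeded from the highest local maxima of the target
#' curve (a single maximum is split by +/- one decade in tau for a
#' two-mode fit), and a small number of jittered restarts with a fixed
#' seed guards against local minima.  eps_inf does not enter either loss
#' target; it is recovered afterwards as the mean offset between the
#' measured eps' and the real part of the fitted modes.
#'
#' @param spectrum a [dielectric_spectrum()]; `eps_der` is computed on the
#'   fly (default settings) if needed.
#' @param n_modes 1 or 2.
#' @param fit_target `"eps_der"` or `"eps_imag"`.
#' @param freq_window length-2 numeric, Hz range to fit (default: all).
#' @param n_restarts jittered restarts after the seeded start.
#' @param seed RNG seed for the restart jitter.
#' @param start optional warm start: an `hn_fit` whose parameters seed the
#'   optimiser.
#' @return An object of class `hn_fit`: eps_inf, `modes` (ordered by
#'   descending tau_hn), `residual_rms`, `converged`, `at_bounds`,
#'   `fit_target`, `freq_window`, `temperature`.
#' @examples
#' f <- 10^seq(-1, 6, by = 0.1)
#' truth <- hn_mode(1.5, 1e-3, 0.85, 0.7)
#' ev <- hn_eval(2.5, list(truth), f)
#' sp <- dielectric_spectrum(110, f, ev$eps_real, ev$eps_imag)
#' fit <- fit_hn(sp, n_modes = 1, fit_target = "eps_imag")
#' @export
fit_hn <- function(spectrum, n_modes = 1L,
                   fit_target = c("eps_der", "eps_imag"),
                   freq_window = NULL, n_restarts = 3L, seed = 101L,
                   start = NULL) {
  stopifnot(inherits(spectrum, "dielectric_spectrum"))
  fit_target <- match.arg(fit_target)
  n_modes <- as.integer(n_modes)
  stopifnot(n_modes %in% c(1L, 2L))
  if (fit_target == "eps_der" && is.null(spectrum$eps_der))
    spectrum <- log_derivative(spectrum)
  f <- spectrum$frequencies
  keep <- if (is.null(freq_window)) rep(TRUE, length(f))
          else f >= freq_window[1] & f <= freq_window[2]
  if (sum(keep) < 8L)
    stop("fit window must contain at least 8 frequency points")
  fw <- f[keep]
  yobs <- if (fit_target == "eps_der") spectrum$eps_der[keep]
          else spectrum$eps_imag[keep]

  model_curve <- function(modes) {
    if (fit_target == "eps_der") hn_deriv_loss(modes, fw)
    else hn_eval(0, modes, fw)$eps_imag
  }
  # parameter vector: per mode (log10 delta_eps, log10 tau, alpha, beta)
  unpack <- function(p) {
    lapply(seq_len(n_modes), function(k) {
      q <- p[(4 * k - 3):(4 * k)]
      hn_mode(10^q[1], 10^q[2], q[3], q[4])
    })
  }
  resid_fun <- function(p) model_curve(unpack(p)) - yobs

  lt_lo <- -log10(2 * pi * max(fw)) - 3
  lt_hi <- -log10(2 * pi * min(fw)) + 3
  lower <- rep(c(-6, lt_lo, 0.05, 0.05), n_modes)
  upper <- rep(c(4, lt_hi, 1, 1), n_modes)

  starts <- hn_starts(fw, yobs, n_modes, start)
  best <- NULL
  withr::with_seed(seed, {
    for (r in 0:n_restarts) {
      p0 <- if (r == 0) starts
            else pmin(pmax(starts + stats::rnorm(length(starts),
                                                 sd = c(0.2, 0.4, 0.05, 0.05)),
                           lower), upper)
      res <- tryCatch(
        minpack.lm::nls.lm(par = pmin(pmax(p0, lower), upper),
                           lower = lower, upper = upper, fn = resid_fun,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 300, ftol = 1e-14, ptol = 1e-14)),
        error = function(e) NULL)
      if (!is.null(res)) {
        ssr <- sum(res$fvec^2)
        if (is.null(best) || ssr < best$ssr)
          best <- list(fit = res, ssr = ssr)
      }
    }
  })
  if (is.null(best))
    stop("HN fit failure: optimiser did not return a result")

  p <- best$fit$par
  modes <- unpack(p)
  ord <- order(vapply(modes, `[[`, numeric(1), "tau_hn"), decreasing = TRUE)
  modes <- modes[ord]
  # alpha = 1 / beta = 1 are legitimate shapes (Cole-Cole / Debye), so only
  # pins at the technical bounds (strength, tau range, lower shape bounds)
  # count as a boundary condition
  shape_upper <- rep(c(FALSE, FALSE, TRUE, TRUE), n_modes)
  at_bounds <- any(abs(p - lower) < 1e-6) ||
    any(abs(upper - p)[!shape_upper] < 1e-6)
  if (at_bounds)
    warning("HN fit: parameter(s) pinned at bounds")
  converged <- best$fit$info %in% 1:4
  # eps_inf from the offset of eps' over the window
  er_model <- hn_eval(0, modes, fw)$eps_real
  eps_inf <- max(0, mean(spectrum$eps_real[keep] - er_model))
  structure(
    list(eps_inf = eps_inf, modes = modes,
         residual_rms = sqrt(mean(best$fit$fvec^2)),
         converged = converged, at_bounds = at_bounds,
         fit_target = fit_target,
         freq_window = if (is.null(freq_window)) range(f) else freq_window,
         temperature = spectrum$temperature),
    class = "hn_fit")
}

# Seed parameters from the local maxima of the target curve.
hn_starts <- function(fw, y, n_modes, start = NULL) {
  if (!is.null(start)) {
    p <- unlist(lapply(start$modes, function(m)
      c(log10(m$delta_eps), log10(m$tau_hn), m$alpha_hn, m$beta_hn)))
    if (length(p) == 4 * n_modes) return(p)
    if (length(p) == 4 && n_modes == 2L)     # split a one-mode warm start
      return(c(p + c(-0.3, 1, 0, 0), p + c(0, -1, 0, 0)))
  }
  n <- length(y)
  interior <- 2:(n - 1)
  is_max <- y[interior] > y[interior - 1] & y[interior] >= y[interior + 1]
  peaks <- interior[is_max]
  peaks <- peaks[order(y[peaks], decreasing = TRUE)]
  if (length(peaks) == 0) peaks <- which.max(y)
  mk <- function(i, tau_shift = 0) {
    tau0 <- 1 / (2 * pi * fw[i]) * 10^tau_shift
    de0 <- max(y[i], 1e-4) * 4 / pi     # Debye peak height is pi*de/4
    c(log10(de0), log10(tau0), 0.85, 0.8)
  }
  if (n_modes == 1L) return(mk(peaks[1]))
  if (length(peaks) >= 2L) c(mk(peaks[1]), mk(peaks[2]))
  else c(mk(peaks[1], 1), mk(peaks[1], -1))
}

#' @export
print.hn_fit <- function(x, ...) {
  cat(sprintf("hn_fit (%s, %s): eps_inf = %.4g, residual rms = %.3g\n",
              x$fit_target,
              if (x$converged) "converged" else "NOT converged",
              x$eps_inf, x$residual_rms))
  for (k in seq_along(x$modes)) {
    m <- x$modes[[k]]
    cat(sprintf(
      "  mode %d: delta_eps = %.4g, tau_hn = %.4g s, alpha = %.3f, beta = %.3f\n",
      k, m$delta_eps, m$tau_hn, m$alpha_hn, m$beta_hn))
  }
  invisible(x)
}
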