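#' Dielectric isotherm spectrum
#'
#' Container for one isothermal frequency sweep of the complex permittivity
#' eps*(F) = eps'(F) - i eps''(F).  Frequencies must be strictly ascending
#' and positive; at least five points are required so that local
#' derivative estimates are defined.
#'
#' @param temperature isotherm temperature, degC.
#' @param frequencies field frequencies F, Hz, strictly increasing.
#' @param eps_real real part eps' (dimensionless), all > 0.
#' @param eps_imag imaginary part eps'' (dimensionless).
#' @param eps_der optional conduction-free loss eps''_der (filled by
#'   [log_derivative()]).
#' @return An object of class `dielectric_spectrum`: a list with the five
#'   fields above.
#' @examples
#' f <- 10^seq(-1, 6, by = 0.1)
#' ev <- hn_eval(3, list(hn_mode(2, 1e-3)), f)
#' sp <- dielectric_spectrum(110, f, ev$eps_real, ev$eps_imag)
#' @export
dielectric_spectrum <- function(temperature, frequencies, eps_real, eps_imag,
                                eps_der = NULL) {
  n <- length(frequencies)
  if (n < 5L)
    stop("a dielectric spectrum needs at least 5 frequency points")
  if (length(eps_real) != n || length(eps_imag) != n)
    stop("frequencies, eps_real and eps_imag must have equal length")
  if (any(!is.finite(frequencies)) || any(frequencies <= 0))
    stop("frequencies must be finite and > 0")
  if (any(diff(frequencies) <= 0))
    stop("frequencies must be strictly increasing")
  if (any(!is.finite(eps_real)) || any(eps_real <= 0))
    stop("eps_real must be finite and > 0")
  if (!is.null(eps_der) && length(eps_der) != n)
    stop("eps_der must match the frequency grid")
  structure(
    list(temperature = as.numeric(temperature),
         frequencies = as.numeric(frequencies),
         eps_real = as.numeric(eps_real),
         eps_imag = as.numeric(eps_imag),
         eps_der = if (is.null(eps_der)) NULL else as.numeric(eps_der)),
    class = "dielectric_spectrum")
}

#' @export
print.dielectric_spectrum <- function(x, ...) {
  cat(sprintf(
    "dielectric_spectrum: %d points, %.3g-%.3g Hz at %.1f degC%s\n",
    length(x$frequencies), min(x$frequencies), max(x$frequencies),
    x$temperature,
    if (is.null(x$eps_der)) "" else " (eps''_der computed)"))
  invisible(x)
}

#' Conduction-free dielectric loss by the logarithmic derivative
#'
#' Computes eps''_der = -(pi/2) d eps'(omega) / d ln(omega), the
#' ohmic-conduction-free estimate of the dielectric loss.  Because it is
#' computed from the real part only, an ohmic term sigma/(eps0 omega) in
#' eps'' leaves the result untouched, and overlapping relaxations are
#' better resolved than in raw eps''.
#'
#' The real part is resampled onto a uniform log10-frequency grid
#' (`points_per_decade`) by linear interpolation, the derivative is taken
#' by a local quadratic (Savitzky-Golay style) fit over
#' `smoothing_window` grid points, and the result is interpolated back to
#' the original frequencies.
#'
#' @param spectrum a [dielectric_spectrum()].
#' @param smoothing_window odd integer >= 5, width of the local quadratic
#'   fit in grid points.
#' @param points_per_decade resampling density of the uniform log grid.
#' @return The spectrum with `eps_der` filled.
#' @examples
#' f <- 10^seq(-1, 6, by = 0.05)
#' ev <- hn_eval(3, list(hn_mode(2, 1e-3)), f)
#' sp <- dielectric_spectrum(110, f, ev$eps_real, ev$eps_imag)
#' sp <- log_derivative(sp)
#' @export
log_derivative <- function(spectrum, smoothing_window = 5L,
                           points_per_decade = 20L) {
  stopifnot(inherits(spectrum, "dielectric_spectrum"))
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 5L || smoothing_window %% 2L == 0L)
    stop("smoothing_window must be an odd integer >= 5")
  lf <- log10(spectrum$frequencies)
  if (length(lf) < smoothing_window)
    stop("insufficient data: fewer frequency points than smoothing_window")
  grid <- seq(min(lf), max(lf), by = 1 / points_per_decade)
  if (length(grid) < smoothing_window)
    grid <- seq(min(lf), max(lf), length.out = smoothing_window)
  y <- stats::approx(lf, spectrum$eps_real, xout = grid)$y
  slope <- local_poly_slope(grid, y, smoothing_window, degree = 3L)
  # d/dln(omega) = d/dln(F) = (1/ln 10) d/dlog10(F)
  der_grid <- -(pi / 2) * slope / log(10)
  eps_der <- stats::approx(grid, der_grid, xout = lf, rule = 2)$y
  spectrum$eps_der <- eps_der
  spectrum
}

# Slope of a least-squares local polynomial fitted over a sliding window,
# evaluated at each point (windows clipped at the edges, so edge estimates
# are one-sided fits).  Degree 3 keeps the slope bias at O(h^4) on smooth
# curves; degree 2 is smoother against noise and used for thermograms.
local_poly_slope <- function(x, y, window, degree = 2L) {
  n <- length(x)
  k <- (window - 1L) %/% 2L
  degree <- min(degree, window - 2L)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - k); hi <- min(n, i + k)
    if (hi - lo + 1L < window) {           # clipped: shift window inward
      lo <- max(1L, min(lo, n - window + 1L))
      hi <- min(n, lo + window - 1L)
    }
    xi <- x[lo:hi] - x[i]
    yi <- y[lo:hi]
    X <- outer(xi, 0:degree, `^`)
    cf <- stats::lm.fit(X, yi)$coefficients
    out[i] <- cf[2L]
  }
  out
}
local_quadratic_slope <- function(x, y, window)
  local_poly_slope(x, y, window, degree = 2L)

#' Loss normalised by the real permittivity
#'
#' Elementwise ratio eps''_der / eps', used to compare spectra of powder
#' samples whose capacitor filling (and hence signal magnitude) differs.
#' Like tan(delta), the normalisation shifts the apparent peak towards
#' higher frequency relative to eps''_der itself.
#'
#' @param spectrum a [dielectric_spectrum()] with `eps_der` computed.
#' @return Numeric vector eps''_der / eps' on the spectrum's frequency grid.
#' @export
normalize_loss <- function(spectrum) {
  stopifnot(inherits(spectrum, "dielectric_spectrum"))
  if (is.null(spectrum$eps_der))
    stop("eps_der has not been computed; call log_derivative() first")
  spectrum$eps_der / spectrum$eps_real
}

#' Complex dielectric modulus
#'
#' M*(omega) = 1/eps*(omega); with eps* = eps' - i eps'',
#' M' = eps'/(eps'^2 + eps''^2) and M'' = eps''/(eps'^2 + eps''^2).
#' M'' is insensitive to electrode polarisation and exhibits a conductivity
#' peak at low frequency, which makes it a useful cross-check that a
#' low-frequency shoulder in eps''_der is a genuine relaxation.
#'
#' @param spectrum a [dielectric_spectrum()].
#' @return A list with components `m_real` and `m_imag`.
#' @export
modulus_transform <- function(spectrum) {
  stopifnot(inherits(spectrum, "dielectric_spectrum"))
  mag2 <- spectrum$eps_real^2 + spectrum$eps_imag^2
  if (any(mag2 == 0))
    stop("zero-magnitude permittivity: modulus undefined")
  list(m_real = spectrum$eps_real / mag2,
       m_imag = spectrum$eps_imag / mag2)
}

#' Relaxation point
#'
#' One (temperature, log10 tau_max) pair extracted from a loss curve, the
#' unit of data consumed by [fit_vtfh()].
#'
#' @param temperature degC.
#' @param log10_tau log10 of tau_max in seconds.
#' @param label one of `"alpha"`, `"alpha1"`, `"alpha2"` (alpha1 is the
#'   low-frequency / longer-tau component).
#' @param method `"peak-pick"` or `"hn-fit"`.
#' @return A one-row data frame of class `relaxation_point`.
#' @export
relaxation_point <- function(temperature, log10_tau, label = "alpha",
                             method = "peak-pick") {
  label <- match.arg(label, c("alpha", "alpha1", "alpha2"))
  method <- match.arg(method, c("peak-pick", "hn-fit"))
  if (!is.finite(log10_tau)) stop("log10_tau must be finite")
  structure(
    data.frame(temperature = temperature, log10_tau = log10_tau,
               label = label, method = method,
               stringsAsFactors = FALSE),
    class = c("relaxation_point", "data.frame"))
}

#' Relaxation time from the maximum of a loss curve
#'
#' Locates the interior maximum of a loss curve over frequency, refines the
#' peak position with a parabola through the three points around the
#' discrete maximum (in log10 F, so the result does not depend on grid
#' placement), and converts via tau_max = 1/(2 pi F_max).
#'
#' @param loss_curve numeric vector (e.g. `eps_der` or a normalised loss)
#'   on `frequencies`.
#' @param frequencies Hz, same length as `loss_curve`.
#' @param temperature degC, recorded in the output.
#' @param label,method passed to [relaxation_point()].
#' @return A [relaxation_point()].
#' @examples
#' f <- 10^seq(0, 3, by = 0.05)
#' ev <- hn_eval(3, list(hn_mode(1, 1 / (2 * pi * 14))), f)
#' pick_peak_tau(ev$eps_imag, f, 110)   # log10 tau ~ -1.94
#' @export
pick_peak_tau <- function(loss_curve, frequencies, temperature,
                          label = "alpha", method = "peak-pick") {
  n <- length(loss_curve)
  stopifnot(length(frequencies) == n, n >= 3)
  i <- which.max(loss_curve)
  if (i == 1L || i == n)
    stop("boundary peak: loss maximum lies on the edge of the frequency window")
  lf <- log10(frequencies[(i - 1):(i + 1)])
  yv <- loss_curve[(i - 1):(i + 1)]
  # exact quadratic through the three points; vertex = -b/(2a)
  cf <- solve(cbind(1, lf, lf^2), yv)
  lf_max <- if (abs(cf[3]) > 0) -cf[2] / (2 * cf[3]) else lf[2]
  # guard against degenerate curvature sending the vertex far away
  if (lf_max < lf[1] || lf_max > lf[3]) lf_max <- lf[2]
  relaxation_point(temperature, -log10(2 * pi) - lf_max, label, method)
}
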