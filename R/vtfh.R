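#' Vogel-Tammann-Fulcher-Hesse parameters
#'
#' Parameters of the super-Arrhenius law
#' log10 tau(T) = log10 tau_inf + B / (ln(10) (T - T0)),
#' with T in Kelvin internally; `t0` is accepted and reported in degC.
#' The pre-exponent log10 tau_inf is conventionally fixed at -14
#' (tau_inf ~ 1e-14 s, a phonon time).
#'
#' @param B curvature parameter, Kelvin, > 0.
#' @param t0 Vogel temperature, degC, below the lowest data temperature.
#' @param log_tau_inf log10 of tau_inf in seconds (<= -10).
#' @param se_B,se_t0 standard errors (optional).
#' @return An object of class `vtfh_params`.
#' @export
vtfh_params <- function(B, t0, log_tau_inf = -14,
                        se_B = NA_real_, se_t0 = NA_real_) {
  if (!is.finite(B) || B <= 0) stop("B must be > 0")
  if (log_tau_inf > -10)
    stop("log_tau_inf must be <= -10 (a microscopic attempt time)")
  structure(list(B = B, t0 = t0, log_tau_inf = log_tau_inf,
                 se_B = se_B, se_t0 = se_t0),
            class = "vtfh_params")
}

#' @export
print.vtfh_params <- function(x, ...) {
  cat(sprintf(
    "vtfh_params: B = %.4g K, T0 = %.4g degC, log10 tau_inf = %g\n",
    x$B, x$t0, x$log_tau_inf))
  invisible(x)
}

#' Evaluate a VTFH law
#'
#' @param params a [vtfh_params()].
#' @param temperature degC (vectorised); must exceed the Vogel temperature.
#' @return log10 tau in seconds; strictly decreasing in temperature.
#' @examples
#' vtfh_eval(vtfh_params(B = 1729, t0 = 10), 90)
#' @export
vtfh_eval <- function(params, temperature) {
  stopifnot(inherits(params, "vtfh_params"))
  tK <- celsius_to_kelvin(temperature)
  t0K <- celsius_to_kelvin(params$t0)
  if (any(tK <= t0K))
    stop("temperature must be above the Vogel temperature T0")
  params$log_tau_inf + params$B / (log(10) * (tK - t0K))
}

#' Fit a VTFH law to relaxation points
#'
#' Unweighted least squares in log10 tau by bounded Levenberg-Marquardt.
#' With `fix_log_tau_inf = TRUE` (the convention adopted for comparing
#' behaviour laws across compositions) only (B, T0) are free.
#'
#' @param points data frame with columns `temperature` (degC) and
#'   `log10_tau` (e.g. rbind-ed [relaxation_point()]s), at least 4 points
#'   spanning at least 20 degC.
#' @param fix_log_tau_inf fix the pre-exponent at `log_tau_inf`?
#' @param log_tau_inf value used when fixed (default -14).
#' @return A [vtfh_params()] with standard errors from the Jacobian.
#' @export
fit_vtfh <- function(points, fix_log_tau_inf = TRUE, log_tau_inf = -14) {
  tC <- points$temperature
  y <- points$log10_tau
  ok <- is.finite(tC) & is.finite(y)
  tC <- tC[ok]; y <- y[ok]
  if (length(tC) < 4L)
    stop("VTFH fit needs at least 4 relaxation points")
  if (diff(range(tC)) < 20)
    stop("VTFH fit needs points spanning at least 20 degC")
  tK <- celsius_to_kelvin(tC)

  resid_fun <- function(p) {
    lti <- if (fix_log_tau_inf) log_tau_inf else p[3]
    lti + p[1] / (log(10) * (tK - p[2])) - y
  }
  # initial values: T0 a few tens of K below the data, B from the median point
  t0_init <- min(tK) - 50
  b_init <- stats::median((y - log_tau_inf) * log(10) * (tK - t0_init))
  p0 <- c(max(b_init, 100), t0_init)
  lower <- c(1, 0); upper <- c(1e5, min(tK) - 1)
  if (!fix_log_tau_inf) {
    p0 <- c(p0, log_tau_inf); lower <- c(lower, -20); upper <- c(upper, -10)
  }
  fit <- minpack.lm::nls.lm(
    par = p0, lower = lower, upper = upper, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 500,
                                         ftol = 1e-14, ptol = 1e-14))
  if (!(fit$info %in% 1:4))
    stop("VTFH fit did not converge (best residual rms ",
         signif(sqrt(mean(fit$fvec^2)), 3), ")")
  p <- fit$par
  if (p[2] >= min(tK) - 1 + 1e-8)
    stop("VTFH fit failure: T0 pinned at the data range")
  dof <- length(y) - length(p)
  se <- rep(NA_real_, length(p))
  if (dof > 0) {
    s2 <- sum(fit$fvec^2) / dof
    cv <- tryCatch(s2 * solve(fit$hessian), error = function(e) NULL)
    if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  }
  vtfh_params(B = p[1], t0 = kelvin_to_celsius(p[2]),
              log_tau_inf = if (fix_log_tau_inf) log_tau_inf else p[3],
              se_B = se[1], se_t0 = se[2])
}

#' Dynamic glass-transition temperature from a VTFH law
#'
#' Inverts the VTFH law at a reference relaxation time (conventionally
#' tau = 100 s): T = T0 + B / ((log10 tau_ref - log10 tau_inf) ln 10).
#'
#' @param params a [vtfh_params()].
#' @param tau_ref reference relaxation time, seconds (default 100 s; some
#'   fields use 10-1000 s conventions).
#' @return Temperature in degC at which tau reaches `tau_ref`.
#' @examples
#' tg_from_vtfh(vtfh_params(B = 3145, t0 = 14.2))  # ~99.5 degC
#' @export
tg_from_vtfh <- function(params, tau_ref = 100) {
  stopifnot(inherits(params, "vtfh_params"))
  lref <- log10(tau_ref)
  if (lref <= params$log_tau_inf)
    stop("tau_ref must exceed the tau_inf scale")
  t0K <- celsius_to_kelvin(params$t0)
  kelvin_to_celsius(t0K + params$B / ((lref - params$log_tau_inf) * log(10)))
}

#' Fragility (steepness) index
#'
#' m = d log10 tau / d(Tg/T) at T = Tg, which for a VTFH law is
#' m = B Tg / (ln(10) (Tg - T0)^2) with all temperatures in Kelvin.
#' Values near 16 indicate Arrhenius ("strong") behaviour and values up to
#' ~170 the most "fragile" glass-formers; a warning is emitted outside
#' that range.
#'
#' @param params a [vtfh_params()].
#' @param tg glass-transition temperature, degC (e.g. from
#'   [tg_from_vtfh()]).
#' @return The dimensionless fragility index.
#' @examples
#' p <- vtfh_params(B = 1729, t0 = 10)
#' fragility_index(p, tg_from_vtfh(p))  # ~114
#' @export
fragility_index <- function(params, tg) {
  stopifnot(inherits(params, "vtfh_params"))
  tgK <- celsius_to_kelvin(tg)
  t0K <- celsius_to_kelvin(params$t0)
  if (tgK <= t0K) stop("Tg must be above T0")
  m <- params$B * tgK / (log(10) * (tgK - t0K)^2)
  if (m < 16 || m > 170)
    warning("fragility index ", signif(m, 3),
            " is outside the expected 16-170 range")
  m
}

#' Estimate the composition of an amorphous phase from its relaxation time
#'
#' Given reference VTFH laws for known drug weight fractions, the
#' relaxation time measured at one temperature locates the composition of
#' an unknown amorphous phase on the Arrhenius diagram: log10 tau is
#' interpolated linearly across composition at the fixed temperature and
#' inverted.  The estimate is bracketed by the two neighbouring reference
#' compositions.
#'
#' @param log10_tau measured log10 tau, seconds.
#' @param temperature degC.
#' @param references named list mapping drug weight fraction (names coercible
#'   to numeric) to [vtfh_params()]; at least two, and log10 tau must be
#'   monotone in composition at `temperature`.
#' @return list with `x_tfd`, `bracket` (length-2), `reference_set`.
#' @examples
#' refs <- vtfh_reference_set(c(0.49, 0.70, 0.90, 1.0))
#' estimate_composition(-1.94, 90, refs)
#' @export
estimate_composition <- function(log10_tau, temperature, references) {
  xs <- as.numeric(names(references))
  if (length(xs) < 2L || any(is.na(xs)))
    stop("references must be a named list of >= 2 vtfh_params, ",
         "names giving the weight fraction")
  ord <- order(xs)
  xs <- xs[ord]; references <- references[ord]
  lt <- vapply(references, vtfh_eval, numeric(1), temperature = temperature)
  d <- diff(lt)
  if (!(all(d > 0) || all(d < 0)))
    stop("reference log10 tau values are not monotone in composition at ",
         temperature, " degC")
  clamped <- FALSE
  if (log10_tau > max(lt) || log10_tau < min(lt)) {
    warning("query log10 tau outside the reference envelope; ",
            "bracket clamped to the nearest edge")
    clamped <- TRUE
  }
  x_hat <- stats::approx(lt, xs, xout = log10_tau, rule = 2)$y
  i <- findInterval(x_hat, xs, rightmost.closed = TRUE,
                    all.inside = TRUE)
  bracket <- c(xs[i], xs[i + 1])
  if (clamped) bracket <- rep(xs[which.min(abs(xs - x_hat))], 2)
  list(x_tfd = x_hat, bracket = bracket,
       reference_set = paste(format(xs), collapse = ","))
}

#' Reference VTFH curves from the packaged TFD/PVP table
#'
#' Convenience constructor of the `references` argument of
#' [estimate_composition()]: picks, for each requested composition, the
#' packaged VTFH parameters of the alpha mode (or the alpha2 component of
#' the majority phase where the relaxation is split).
#'
#' @param x_tfd weight fractions to include (must exist in
#'   [tfd_pvp_vtfh]).
#' @param component `"alpha2"` (default, the majority-phase component
#'   where split) or `"alpha1"`.
#' @return Named list of [vtfh_params()].
#' @export
vtfh_reference_set <- function(x_tfd = c(0, 0.10, 0.30, 0.49, 0.70, 0.90, 1),
                               component = c("alpha2", "alpha1")) {
  component <- match.arg(component)
  tab <- asdtherm::tfd_pvp_vtfh
  out <- list()
  for (x in x_tfd) {
    rows <- tab[tab$x_tfd == x, ]
    if (nrow(rows) == 0) stop("no packaged VTFH row for x = ", x)
    row <- if (nrow(rows) == 1L) rows else rows[rows$mode == component, ]
    if (nrow(row) != 1L) stop("no ", component, " row for x = ", x)
    out[[format(x)]] <- vtfh_params(B = row$B_K, t0 = row$T0_C,
                                    se_B = row$B_se_K, se_t0 = row$T0_se_C)
  }
  out
}
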