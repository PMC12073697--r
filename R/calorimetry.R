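#' Reversible heat-capacity thermogram
#'
#' One temperature scan of the reversible specific heat (J g^-1 degC^-1)
#' as separated by temperature-modulated DSC.  Raw reversible heat flow
#' (mW/mg at a known heating rate) converts to specific heat by a
#' reader-level scale factor.
#'
#' @param temperatures degC, strictly increasing, >= 20 points.
#' @param rev_cp reversible specific heat, J g^-1 degC^-1.
#' @return An object of class `thermogram`.
#' @export
thermogram <- function(temperatures, rev_cp) {
  n <- length(temperatures)
  if (n < 20L) stop("a thermogram needs at least 20 points")
  if (length(rev_cp) != n) stop("temperatures and rev_cp lengths differ")
  if (any(diff(temperatures) <= 0))
    stop("temperatures must be strictly increasing")
  structure(list(temperatures = as.numeric(temperatures),
                 rev_cp = as.numeric(rev_cp)),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("thermogram: %d points, %.1f-%.1f degC\n",
              length(x$temperatures), min(x$temperatures),
              max(x$temperatures)))
  invisible(x)
}

#' Glass transition extracted from a thermogram
#'
#' @param tg_onset,tg_midpoint,tg_end characteristic temperatures, degC,
#'   strictly ordered.
#' @param delta_cp Cp-jump magnitude at the midpoint, J g^-1 degC^-1, > 0.
#' @return An object of class `glass_transition`.
#' @export
glass_transition <- function(tg_onset, tg_midpoint, tg_end, delta_cp) {
  if (!(tg_onset < tg_midpoint && tg_midpoint < tg_end))
    stop("need tg_onset < tg_midpoint < tg_end")
  if (delta_cp <= 0) stop("delta_cp must be > 0")
  structure(list(tg_onset = tg_onset, tg_midpoint = tg_midpoint,
                 tg_end = tg_end, delta_cp = delta_cp),
            class = "glass_transition")
}

#' @export
print.glass_transition <- function(x, ...) {
  cat(sprintf(
    "glass_transition: onset %.1f, midpoint %.1f, end %.1f degC; dCp = %.3f J/g/degC\n",
    x$tg_onset, x$tg_midpoint, x$tg_end, x$delta_cp))
  invisible(x)
}

#' Extract the glass transition from a thermogram
#'
#' Locates the Cp-jump by the peak of the smoothed temperature derivative
#' of the reversible heat capacity.  The midpoint is the
#' parabolically-refined derivative maximum; baselines are fitted linearly
#' over flat windows flanking the step, the Cp-jump is their difference
#' extrapolated to the midpoint, and onset/end are the intersections of
#' the baselines with the tangent at the midpoint.
#'
#' If no derivative peak exceeds the slope threshold the thermogram is
#' declared transition-free (error).  If two resolved peaks are found,
#' both transitions are returned as a list with class
#' `multiple_transitions`.
#'
#' @param tg a [thermogram()].
#' @param smoothing_window odd integer, derivative smoothing width in
#'   points; the default covers about 2 degC of data (clamped to 7-31
#'   points), matched to the few-degC width of a calorimetric glass
#'   transition.
#' @param baseline_width width of the flanking baseline fit windows, degC.
#' @param min_slope minimum derivative-peak height treated as a real
#'   transition, J g^-1 degC^-2.
#' @param min_separation degC; derivative maxima closer than this are
#'   treated as one transition (the strongest wins).
#' @return A [glass_transition()], or a `multiple_transitions` list of
#'   them when two resolved steps are present.
#' @export
extract_glass_transition <- function(tg, smoothing_window = NULL,
                                     baseline_width = 10,
                                     min_slope = 0.005,
                                     min_separation = 8) {
  stopifnot(inherits(tg, "thermogram"))
  tt <- tg$temperatures
  cp <- tg$rev_cp
  if (is.null(smoothing_window)) {
    smoothing_window <- round(2 / mean(diff(tt)))
    smoothing_window <- min(max(smoothing_window, 7L), 31L)
  }
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window %% 2L == 0L)
    smoothing_window <- smoothing_window + 1L
  d <- local_quadratic_slope(tt, cp, max(5L, smoothing_window))
  noise <- stats::mad(d, constant = 1.4826)
  thr <- max(min_slope, 6 * noise)
  n <- length(tt)
  interior <- 2:(n - 1)
  cand <- interior[d[interior] > thr &
                   d[interior] >= d[interior - 1] &
                   d[interior] >= d[interior + 1]]
  if (length(cand) == 0)
    stop("no glass transition: no derivative peak above the noise threshold")
  # merge candidates into resolved transitions: a second peak counts only
  # if it is far enough away AND the derivative drops to below half of the
  # smaller peak somewhere in between (prominence), so noise ripples on a
  # step's flanks do not split it
  cand <- cand[order(d[cand], decreasing = TRUE)]
  peaks <- integer(0)
  for (i in cand) {
    resolved <- TRUE
    for (j in peaks) {
      rng <- if (i < j) i:j else j:i
      valley <- min(d[rng])
      if (abs(tt[i] - tt[j]) <= min_separation ||
          valley > 0.5 * min(d[i], d[j])) { resolved <- FALSE; break }
    }
    if (resolved) peaks <- c(peaks, i)
  }
  peaks <- sort(peaks)
  res <- lapply(peaks, function(i)
    tangent_construction(tt, cp, d, i, baseline_width))
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0)
    stop("no glass transition: tangent construction failed at every peak")
  if (length(res) == 1L) return(res[[1]])
  structure(res, class = "multiple_transitions")
}

# Tangent construction around one derivative peak.
tangent_construction <- function(tt, cp, d, i, baseline_width) {
  n <- length(tt)
  # refine the midpoint with a parabola fitted to the derivative over a
  # +/- 2 degC window around the discrete peak (stable against noise)
  t_mid <- tt[i]; s_mid <- d[i]
  win <- abs(tt - tt[i]) <= max(2, 3 * mean(diff(tt)))
  if (sum(win) >= 5) {
    xs <- tt[win] - tt[i]; ys <- d[win]
    cf <- tryCatch(stats::lm.fit(cbind(1, xs, xs^2), ys)$coefficients,
                   error = function(e) NULL)
    if (!is.null(cf) && is.finite(cf[3]) && cf[3] < 0) {
      tv <- -cf[2] / (2 * cf[3])
      if (abs(tv) <= max(2, 3 * mean(diff(tt)))) {
        t_mid <- tt[i] + tv
        s_mid <- cf[1] + cf[2] * tv + cf[3] * tv^2
      }
    }
  }
  # step extent from where the derivative falls to 10% of the peak, widened
  # by half its half-width so the baselines sit clear of the step's tails
  lo <- i; while (lo > 1 && d[lo] > 0.1 * d[i]) lo <- lo - 1
  hi <- i; while (hi < n && d[hi] > 0.1 * d[i]) hi <- hi + 1
  t_lo <- tt[lo] - 0.5 * (t_mid - tt[lo])
  t_hi <- tt[hi] + 0.5 * (tt[hi] - t_mid)
  left <- tt >= t_lo - baseline_width & tt <= t_lo
  right <- tt >= t_hi & tt <= t_hi + baseline_width
  if (sum(left) < 3 || sum(right) < 3) return(NULL)
  bl <- stats::lm.fit(cbind(1, tt[left]), cp[left])$coefficients
  br <- stats::lm.fit(cbind(1, tt[right]), cp[right])$coefficients
  delta_cp <- (br[1] + br[2] * t_mid) - (bl[1] + bl[2] * t_mid)
  if (!is.finite(delta_cp) || delta_cp <= 0) return(NULL)
  cp_mid <- stats::approx(tt, cp, xout = t_mid)$y
  # tangent through (t_mid, cp_mid) with slope s_mid
  t_on <- (cp_mid - s_mid * t_mid - bl[1]) / (bl[2] - s_mid)
  t_end <- (cp_mid - s_mid * t_mid - br[1]) / (br[2] - s_mid)
  if (!(t_on < t_mid && t_mid < t_end)) return(NULL)
  glass_transition(unname(t_on), unname(t_mid), unname(t_end),
                   unname(delta_cp))
}

#' Gordon-Taylor state-curve model
#'
#' Tg(x) = (x Tg_drug + K (1-x) Tg_polymer) / (x + K (1-x)) for the glass
#' transition of a drug/polymer blend with drug weight fraction x.
#'
#' @param tg_drug,tg_polymer pure-component Tg midpoints, degC
#'   (`tg_drug < tg_polymer` for the systems modelled here).
#' @param k Gordon-Taylor parameter, > 0.
#' @param se_k standard error of k (optional).
#' @return An object of class `gordon_taylor`.
#' @export
gordon_taylor <- function(tg_drug, tg_polymer, k, se_k = NA_real_) {
  if (!(tg_drug < tg_polymer))
    stop("expected tg_drug < tg_polymer")
  if (!is.finite(k) || k <= 0) stop("k must be > 0")
  structure(list(tg_drug = tg_drug, tg_polymer = tg_polymer,
                 k = k, se_k = se_k),
            class = "gordon_taylor")
}

#' @export
print.gordon_taylor <- function(x, ...) {
  cat(sprintf(
    "gordon_taylor: K = %.3f%s, endpoints %.1f / %.1f degC\n", x$k,
    if (is.na(x$se_k)) "" else sprintf(" +/- %.3f", x$se_k),
    x$tg_drug, x$tg_polymer))
  invisible(x)
}

#' Evaluate the Gordon-Taylor law
#'
#' @param model a [gordon_taylor()].
#' @param x drug weight fraction in [0, 1] (vectorised).
#' @return Blend Tg in degC; equals the pure-component values at x = 0, 1
#'   and decreases monotonically in x when `tg_drug < tg_polymer`.
#' @examples
#' m <- gordon_taylor(60, 106, k = 0.61)
#' gt_eval(m, 0.70)  # ~69.5 degC
#' @export
gt_eval <- function(model, x) {
  stopifnot(inherits(model, "gordon_taylor"))
  if (any(x < 0 | x > 1)) stop("x must be in [0, 1]")
  (x * model$tg_drug + model$k * (1 - x) * model$tg_polymer) /
    (x + model$k * (1 - x))
}

#' Fit the Gordon-Taylor parameter to blend Tg data
#'
#' Least squares over K only, with the pure-component endpoints fixed as
#' constraints: the curve passes through them identically, so endpoint
#' rows (x = 0 or 1) are excluded from the residual.
#'
#' @param points data frame with columns `x_tfd` and `tg_C` (blend Tg
#'   midpoints); at least 3 interior compositions.
#' @param tg_drug,tg_polymer fixed endpoints, degC.
#' @return A [gordon_taylor()] with `se_k` from the Jacobian.
#' @examples
#' gt_fit(data.frame(x_tfd = tfd_pvp_tg$x_tfd,
#'                   tg_C = tfd_pvp_tg$tg_midpoint_C))
#' @export
gt_fit <- function(points, tg_drug = tfd_pvp_constants$tg_drug_C,
                   tg_polymer = tfd_pvp_constants$tg_polymer_C) {
  x <- points$x_tfd; y <- points$tg_C
  keep <- x > 0 & x < 1
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 interior compositions")
  if (length(unique(x)) < 2L) stop("degenerate x values")
  pred <- function(k) (x * tg_drug + k * (1 - x) * tg_polymer) /
    (x + k * (1 - x))
  fit <- minpack.lm::nls.lm(
    par = 1, lower = 1e-3, upper = 100,
    fn = function(p) pred(p[1]) - y,
    control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14))
  k <- fit$par[1]
  h <- 1e-6 * max(k, 1)
  jac <- (pred(k + h) - pred(k - h)) / (2 * h)
  dof <- length(y) - 1L
  se_k <- if (dof > 0)
    sqrt(sum(fit$fvec^2) / dof / sum(jac^2)) else NA_real_
  gordon_taylor(tg_drug, tg_polymer, k, se_k)
}

#' Invert the Gordon-Taylor law
#'
#' Closed-form inversion: x/(1-x) = K (Tg - Tg_polymer)/(Tg_drug - Tg),
#' valid for Tg strictly between the pure-component values.
#'
#' @param model a [gordon_taylor()].
#' @param tg blend Tg, degC, strictly inside (tg_drug, tg_polymer)
#'   (vectorised).
#' @return Drug weight fraction x in (0, 1).
#' @examples
#' gt_invert(gordon_taylor(60, 106, 0.76), 73)  # ~0.66
#' @export
gt_invert <- function(model, tg) {
  stopifnot(inherits(model, "gordon_taylor"))
  if (any(tg <= model$tg_drug | tg >= model$tg_polymer))
    stop("tg must lie strictly between the pure-component values")
  r <- model$k * (tg - model$tg_polymer) / (model$tg_drug - tg)
  r / (1 + r)
}

#' Couchman-Karasz prediction of the Gordon-Taylor parameter
#'
#' For a regular (athermal) solution the Gordon-Taylor parameter should
#' equal the ratio of the pure-component Cp-jumps,
#' K_CK = dCp_polymer / dCp_drug.  Uncertainty is propagated by min-max:
#' k_min = (a - u_a)/(b + u_b), k_max = (a + u_a)/(b - u_b), and the
#' reported uncertainty is the symmetrised half-range.
#'
#' @param delta_cp_polymer,delta_cp_drug Cp-jump magnitudes,
#'   J g^-1 degC^-1, > 0.
#' @param u_polymer,u_drug their uncertainties (default 0).
#' @return list with `k`, `k_min`, `k_max`, `u` (half-range).
#' @examples
#' couchman_karasz(0.34, 0.56, 0.02, 0.01)  # K_CK ~ 0.61 +/- 0.05
#' @export
couchman_karasz <- function(delta_cp_polymer, delta_cp_drug,
                            u_polymer = 0, u_drug = 0) {
  if (delta_cp_polymer <= 0 || delta_cp_drug <= 0)
    stop("Cp jumps must be > 0")
  k <- delta_cp_polymer / delta_cp_drug
  k_min <- (delta_cp_polymer - u_polymer) / (delta_cp_drug + u_drug)
  k_max <- (delta_cp_polymer + u_polymer) / (delta_cp_drug - u_drug)
  list(k = k, k_min = k_min, k_max = k_max, u = (k_max - k_min) / 2)
}

#' Recrystallisation enthalpy accounting
#'
#' Converts a measured recrystallisation exotherm into the fraction of the
#' drug load that crystallised and the composition of the remaining
#' amorphous blend.  With drug weight fraction x and crystallised fraction
#' f, mass balance gives x_remaining = x(1-f) / (x(1-f) + (1-x)).
#'
#' @param x_tfd drug weight fraction of the dispersion, > 0.
#' @param dh_cr_per_g_asd exotherm enthalpy per gram of dispersion,
#'   J g^-1 (give exactly one of this and `dh_cr_per_g_drug`).
#' @param dh_cr_per_g_drug exotherm enthalpy per gram of drug load.
#' @param dh_ref_pure reference enthalpy of the fully-crystallising pure
#'   amorphous drug, J g^-1.
#' @return list of class `recrystallization_result`:
#'   `dh_cr_per_g_asd`, `dh_cr_per_g_drug`, `fraction_crystallized`,
#'   `x_remaining`.
#' @examples
#' recrystallization_accounting(0.90, dh_cr_per_g_drug = 58,
#'                              dh_ref_pure = 76)
#' @export
recrystallization_accounting <- function(x_tfd, dh_cr_per_g_asd = NULL,
                                         dh_cr_per_g_drug = NULL,
                                         dh_ref_pure = tfd_pvp_constants$dh_cr_pure) {
  if (x_tfd <= 0 || x_tfd > 1) stop("x_tfd must be in (0, 1]")
  if (is.null(dh_cr_per_g_asd) == is.null(dh_cr_per_g_drug))
    stop("give exactly one of dh_cr_per_g_asd and dh_cr_per_g_drug")
  if (is.null(dh_cr_per_g_drug))
    dh_cr_per_g_drug <- dh_cr_per_g_asd / x_tfd
  else
    dh_cr_per_g_asd <- dh_cr_per_g_drug * x_tfd
  if (dh_cr_per_g_asd < 0 || dh_ref_pure <= 0)
    stop("enthalpies must be non-negative (reference > 0)")
  f <- dh_cr_per_g_drug / dh_ref_pure
  if (f > 1.05)
    stop("inconsistent enthalpies: implied crystallised fraction ",
         signif(f, 3), " exceeds 1")
  if (f > 1) {
    warning("crystallised fraction ", signif(f, 4), " clamped to 1")
    f <- 1
  }
  x_rem <- if (f == 1 && x_tfd == 1) 0
    else x_tfd * (1 - f) / (x_tfd * (1 - f) + (1 - x_tfd))
  structure(list(dh_cr_per_g_asd = dh_cr_per_g_asd,
                 dh_cr_per_g_drug = dh_cr_per_g_drug,
                 fraction_crystallized = f,
                 x_remaining = x_rem),
            class = "recrystallization_result")
}

#' @export
print.recrystallization_result <- function(x, ...) {
  cat(sprintf(
    "recrystallization: %.1f%% of the drug load crystallised; remaining amorphous blend %.1f wt.%% drug\n",
    100 * x$fraction_crystallized, 100 * x$x_remaining))
  invisible(x)
}
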