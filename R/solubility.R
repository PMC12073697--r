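#' Flory-Huggins solubility model for a drug/polymer pair
#'
#' Lattice-model description of the solubility (liquidus) curve of a
#' crystalline drug in an amorphous polymer:
#' dHm/R (1/Tm - 1/T) = ln(phi) + (1 - 1/lambda)(1 - phi) + chi (1 - phi)^2,
#' where phi is the drug volume fraction and lambda the polymer/drug molar
#' volume ratio lambda = Mw_polymer rho_drug / (rho_polymer M_drug).
#'
#' @param tm_C drug melting temperature, degC.
#' @param dhm_kJ_mol drug melting enthalpy, kJ mol^-1 (converted to J
#'   internally).
#' @param rho_drug,rho_polymer densities, g cm^-3.
#' @param m_drug,mw_polymer molar masses, g mol^-1.
#' @param chi Flory-Huggins interaction parameter (NA until fitted).
#' @param se_chi its standard error.
#' @return An object of class `flory_huggins` with derived `lam` and the
#'   gas constant (8.314 J mol^-1 K^-1).
#' @examples
#' fh <- do.call(flory_huggins, tfd_pvp_constants[
#'   c("tm_C", "dhm_kJ_mol", "rho_drug", "rho_polymer",
#'     "m_drug", "mw_polymer")])
#' @export
flory_huggins <- function(tm_C, dhm_kJ_mol, rho_drug, rho_polymer,
                          m_drug, mw_polymer, chi = NA_real_,
                          se_chi = NA_real_) {
  if (dhm_kJ_mol <= 0) stop("dhm_kJ_mol must be > 0")
  if (rho_drug <= 0 || rho_polymer <= 0) stop("densities must be > 0")
  if (m_drug <= 0 || mw_polymer <= 0) stop("molar masses must be > 0")
  if (celsius_to_kelvin(tm_C) <= 0) stop("tm_C below absolute zero")
  structure(list(tm_C = tm_C, dhm = dhm_kJ_mol * 1000,
                 rho_drug = rho_drug, rho_polymer = rho_polymer,
                 m_drug = m_drug, mw_polymer = mw_polymer,
                 lam = mw_polymer * rho_drug / (rho_polymer * m_drug),
                 chi = chi, se_chi = se_chi, R = 8.314),
            class = "flory_huggins")
}

#' @export
print.flory_huggins <- function(x, ...) {
  cat(sprintf(
    "flory_huggins: Tm = %.1f degC, dHm = %.1f kJ/mol, lambda = %.3f, chi = %s\n",
    x$tm_C, x$dhm / 1000, x$lam,
    if (is.na(x$chi)) "unset" else sprintf("%.3f", x$chi)))
  invisible(x)
}

#' Drug volume fraction from weight fraction
#'
#' phi = (x/rho_drug) / (x/rho_drug + (1-x)/rho_polymer).
#'
#' @param x drug weight fraction in [0, 1] (vectorised).
#' @param model a [flory_huggins()].
#' @return Volume fraction in [0, 1], strictly increasing in x.
#' @export
volume_fraction <- function(x, model) {
  stopifnot(inherits(model, "flory_huggins"))
  if (any(x < 0 | x > 1)) stop("x must be in [0, 1]")
  (x / model$rho_drug) /
    (x / model$rho_drug + (1 - x) / model$rho_polymer)
}

#' Polymer/drug molar volume ratio
#'
#' lambda = Mw_polymer rho_drug / (rho_polymer M_drug), as carried by the
#' model object.
#'
#' @param model a [flory_huggins()].
#' @return The positive scalar lambda.
#' @export
lambda_ratio <- function(model) {
  stopifnot(inherits(model, "flory_huggins"))
  model$lam
}

#' Flory-Huggins residual at a composition/temperature pair
#'
#' residual = LHS - RHS of the solubility equation; it vanishes on the
#' liquidus.  At x = 1 and T = Tm it is identically zero (melting-point
#' anchor), and it is affine in chi with coefficient -(1 - phi)^2.
#'
#' @param x drug weight fraction in (0, 1].
#' @param temperature degC.
#' @param model a [flory_huggins()] with `chi` set (or pass `chi`).
#' @param chi optional override of the model's chi.
#' @return Dimensionless residual (vectorised over `x`/`temperature`).
#' @export
fh_residual <- function(x, temperature, model, chi = model$chi) {
  stopifnot(inherits(model, "flory_huggins"))
  if (any(x <= 0)) stop("x must be > 0 (log of the volume fraction)")
  if (any(is.na(chi))) stop("chi is unset")
  phi <- volume_fraction(x, model)
  tK <- celsius_to_kelvin(temperature)
  tmK <- celsius_to_kelvin(model$tm_C)
  lhs <- model$dhm / model$R * (1 / tmK - 1 / tK)
  rhs <- log(phi) + (1 - 1 / model$lam) * (1 - phi) + chi * (1 - phi)^2
  lhs - rhs
}

#' Solubility temperature at a given composition
#'
#' Solves the Flory-Huggins equation for T at fixed drug weight fraction
#' by bracketed root finding; the left-hand side is strictly increasing in
#' T while the right-hand side is constant, so the root is unique.  As
#' x -> 1 the root approaches the drug melting point.
#'
#' @param x drug weight fraction in (0, 1).
#' @param model a [flory_huggins()] with chi set.
#' @param bracket degC search interval (default Tm - 200 to Tm + 50).
#' @return Temperature in degC, or NA (with a warning) when the residual
#'   does not change sign inside the bracket.
#' @export
solve_solubility_temperature <- function(x, model, bracket = NULL) {
  stopifnot(inherits(model, "flory_huggins"))
  if (x <= 0 || x >= 1) stop("x must be in (0, 1)")
  if (is.null(bracket)) bracket <- c(model$tm_C - 200, model$tm_C + 50)
  bracket[1] <- max(bracket[1], -celsius_to_kelvin(0) + 1)  # stay above 0 K
  fl <- fh_residual(x, bracket[1], model)
  fu <- fh_residual(x, bracket[2], model)
  if (!is.finite(fl) || !is.finite(fu) || fl * fu > 0) {
    warning("no solubility solution: residual does not change sign in [",
            bracket[1], ", ", bracket[2], "] degC")
    return(NA_real_)
  }
  stats::uniroot(function(tc) fh_residual(x, tc, model),
                 interval = bracket, tol = 1e-10)$root
}

#' Fit the Flory-Huggins interaction parameter
#'
#' chi minimising the sum of squared implicit residuals over the
#' saturation points.  Because the residual is affine in chi with slope
#' -(1 - phi)^2, the minimiser is closed-form linear least squares:
#' chi = sum(w r0) / sum(w^2) with w = (1 - phi)^2 and r0 the residual at
#' chi = 0.  The standard error comes from the residual variance.
#'
#' @param points data frame with columns `t_anneal_C` and `x_sat`
#'   (saturation weight fraction reached at each annealing temperature);
#'   at least 2 points.
#' @param model a [flory_huggins()] carrying the melting and density
#'   constants.
#' @return The model with `chi` and `se_chi` filled.
#' @examples
#' fh <- do.call(flory_huggins, tfd_pvp_constants[
#'   c("tm_C", "dhm_kJ_mol", "rho_drug", "rho_polymer",
#'     "m_drug", "mw_polymer")])
#' fit_chi(tfd_pvp_solubility, fh)  # chi ~ -2.3
#' @export
fit_chi <- function(points, model) {
  stopifnot(inherits(model, "flory_huggins"))
  x <- points$x_sat; tC <- points$t_anneal_C
  ok <- is.finite(x) & is.finite(tC)
  x <- x[ok]; tC <- tC[ok]
  if (length(x) < 2L) stop("need at least 2 saturation points")
  phi <- volume_fraction(x, model)
  w <- (1 - phi)^2
  if (sum(w^2) < 1e-12) stop("degenerate points: all at x ~ 1")
  r0 <- fh_residual(x, tC, model, chi = 0)
  chi <- sum(r0 * w) / sum(w^2)
  res <- r0 - chi * w
  dof <- length(x) - 1L
  se <- if (dof > 0) sqrt(sum(res^2) / dof / sum(w^2)) else NA_real_
  model$chi <- chi
  model$se_chi <- se
  model
}

#' Saturation points from annealing/Tg-readback records
#'
#' Implements the annealing protocol readback: after equilibrating a
#' partially crystalline dispersion at an annealing temperature T_a, the
#' measured Tg of the remaining amorphous blend is converted to its drug
#' weight fraction through the inverted Gordon-Taylor state curve, giving
#' one solubility point (T_a, x_sat) per record.
#'
#' @param records data frame with columns `t_anneal_C` and `tg_C`.
#' @param gt_model a [gordon_taylor()].
#' @return data frame ordered by `t_anneal_C` with columns `t_anneal_C`,
#'   `tg_C`, `x_sat`, `error` (NA for good records; Tg values outside the
#'   open Gordon-Taylor interval yield an error message and NA `x_sat`,
#'   other records are still processed).
#' @examples
#' gt <- gordon_taylor(60, 106, 0.76)
#' latreche_points(data.frame(t_anneal_C = 140, tg_C = 73), gt)
#' @export
latreche_points <- function(records, gt_model) {
  stopifnot(inherits(gt_model, "gordon_taylor"))
  out <- records[order(records$t_anneal_C),
                 c("t_anneal_C", "tg_C"), drop = FALSE]
  out$x_sat <- NA_real_
  out$error <- NA_character_
  for (i in seq_len(nrow(out))) {
    res <- tryCatch(gt_invert(gt_model, out$tg_C[i]),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) out$error[i] <- res
    else out$x_sat[i] <- res
  }
  rownames(out) <- NULL
  out
}
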