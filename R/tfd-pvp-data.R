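#' Glass transitions of Terfenadine/PVP K12 dispersions
#'
#' Calorimetric glass-transition temperatures (onset and midpoint of the
#' Cp-jump on the second heating at 5 degC/min) and Cp-jump magnitudes for
#' co-milled Terfenadine (TFD) / PVP K12 amorphous solid dispersions across
#' the full composition range, as used throughout the worked examples.
#'
#' @format A data frame with 7 rows:
#' \describe{
#'   \item{x_tfd}{TFD weight fraction (0 = pure PVP, 1 = pure TFD)}
#'   \item{tg_onset_C}{glass-transition onset, degC (+/- 1 degC)}
#'   \item{tg_midpoint_C}{glass-transition midpoint, degC (+/- 1 degC)}
#'   \item{delta_cp}{Cp-jump magnitude, J g^-1 degC^-1}
#'   \item{delta_cp_se}{its uncertainty, J g^-1 degC^-1}
#' }
#' @seealso [gt_fit()], [couchman_karasz()]
#' @export
tfd_pvp_tg <- data.frame(
  x_tfd         = c(0, 0.10, 0.30, 0.49, 0.70, 0.90, 1),
  tg_onset_C    = c(96, 91, 82, 75, 67, 60, 58),
  tg_midpoint_C = c(106, 99, 90, 81, 72, 64, 60),
  delta_cp      = c(0.34, 0.36, 0.40, 0.45, 0.51, 0.54, 0.56),
  delta_cp_se   = c(0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01)
)

#' Annealing-derived solubility points for TFD in PVP K12
#'
#' Glass-transition midpoints measured after 5 h annealing at `t_anneal_C`
#' of a partially recrystallised 70 wt.% TFD dispersion, and the TFD weight
#' fraction of the remaining amorphous blend read back through the
#' Gordon-Taylor state curve.  These pairs define the experimental
#' solubility (liquidus) points used by [fit_chi()].
#'
#' @format A data frame with 5 rows and columns `t_anneal_C`, `tg_C`,
#'   `x_sat`.
#' @seealso [latreche_points()], [fit_chi()]
#' @export
tfd_pvp_solubility <- data.frame(
  t_anneal_C = c(120, 125, 130, 135, 140),
  tg_C       = c(84, 83, 81, 77, 73),
  x_sat      = c(0.42, 0.44, 0.48, 0.57, 0.66)
)

#' VTFH parameters of the main relaxation of TFD/PVP dispersions
#'
#' Vogel-Tammann-Fulcher-Hesse parameters (with log10 tau_inf fixed at -14)
#' fitted to the temperature evolution of the relaxation time of the alpha
#' mode, or of its alpha_1 (low-frequency) / alpha_2 (high-frequency)
#' components where the main relaxation is split, for each composition.
#' `tg_drs_C` is the tabulated temperature at which tau reaches 100 s and
#' `m` the tabulated fragility index.
#'
#' @format A data frame with 9 rows and columns `x_tfd`, `mode`
#'   (`"alpha"`, `"alpha1"` or `"alpha2"`), `B_K`, `B_se_K`, `T0_C`,
#'   `T0_se_C`, `tg_drs_C`, `m`, `m_se`.
#' @seealso [vtfh_params()], [tg_from_vtfh()], [fragility_index()]
#' @export
tfd_pvp_vtfh <- data.frame(
  x_tfd    = c(0, 0.10, 0.30, 0.49, 0.70, 0.70, 0.90, 0.90, 1),
  mode     = c("alpha", "alpha", "alpha", "alpha",
               "alpha1", "alpha2", "alpha1", "alpha2", "alpha"),
  B_K      = c(3145, 2950, 2851, 2657, 2641, 2006, 2356, 1759, 1729),
  B_se_K   = c(10, 14, 14, 17, 21, 10, 19, 12, 17),
  T0_C     = c(14.2, 17.3, 11.1, 7.6, 0.6, 12.7, 2.0, 11.2, 10),
  T0_se_C  = c(0.4, 0.5, 0.6, 0.6, 0.8, 0.4, 0.6, 0.4, 1),
  tg_drs_C = c(99.5, 97.5, 88.5, 79.5, 70.0, 67.0, 66.0, 59.0, 56.5),
  m        = c(70, 74, 75, 79, 82, 100, 85, 111, 114),
  m_se     = c(3, 3, 3, 4, 5, 5, 5, 7, 7)
)

#' Physical constants of the Terfenadine/PVP K12 system
#'
#' Pure-component quantities used by the solubility and recrystallisation
#' calculations: TFD melting point and enthalpy, densities, molar masses,
#' the recrystallisation enthalpy of fully amorphous milled TFD, and the
#' pure-component glass-transition midpoints.
#'
#' @format A named list:
#' \describe{
#'   \item{tm_C}{TFD melting temperature, degC}
#'   \item{dhm_kJ_mol}{TFD melting enthalpy, kJ mol^-1}
#'   \item{rho_drug, rho_polymer}{densities, g cm^-3}
#'   \item{m_drug, mw_polymer}{molar masses, g mol^-1}
#'   \item{dh_cr_pure}{recrystallisation enthalpy of milled amorphous TFD,
#'     J g^-1}
#'   \item{tg_drug_C, tg_polymer_C}{pure-component Tg midpoints, degC}
#' }
#' @export
tfd_pvp_constants <- list(
  tm_C        = 150,
  dhm_kJ_mol  = 54.2,
  rho_drug    = 1.05,
  rho_polymer = 1.17,
  m_drug      = 471.7,
  mw_polymer  = 2500,
  dh_cr_pure  = 76,
  tg_drug_C   = 60,
  tg_polymer_C = 106
)

# Kelvin offset used everywhere model math runs in absolute temperature
.zeroC <- 273.15

#' Convert between Celsius and Kelvin
#'
#' All model mathematics in the package runs in Kelvin while file and report
#' temperatures are in degrees Celsius; these helpers are the single
#' conversion point.
#'
#' @param x temperature(s) to convert.
#' @return Converted temperature(s).
#' @export
celsius_to_kelvin <- function(x) x + .zeroC

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(x) x - .zeroC
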