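# Shared fixtures: everything is generated in code, no stored data.

# log-spaced frequency grid, points per decade
freq_grid <- function(lo = -1, hi = 6, ppd = 10) 10^seq(lo, hi, by = 1 / ppd)

# spectrum of a known HN model (+ optional ohmic conduction)
model_spectrum <- function(modes, eps_inf = 3, f = freq_grid(),
                           temperature = 110, c_cond = 0) {
  ev <- hn_eval(eps_inf, modes, f)
  ei <- ev$eps_imag + if (c_cond > 0) c_cond / (2 * pi * f) else 0
  dielectric_spectrum(temperature, f, ev$eps_real, ei)
}

# indices of interior local maxima
local_maxima <- function(y) {
  n <- length(y)
  i <- 2:(n - 1)
  i[y[i] > y[i - 1] & y[i] >= y[i + 1]]
}

# Flory-Huggins model preloaded with the packaged drug/polymer constants
tfd_pvp_fh <- function(chi = NA_real_) {
  k <- tfd_pvp_constants
  flory_huggins(k$tm_C, k$dhm_kJ_mol, k$rho_drug, k$rho_polymer,
                k$m_drug, k$mw_polymer, chi = chi)
}
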