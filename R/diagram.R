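#' Build the combined phase-and-state diagram
#'
#' Tabulates the Gordon-Taylor state curve (blend Tg) and the
#' Flory-Huggins solubility (liquidus) curve on a common composition
#' grid, together with experimental overlays.  Solubility temperatures
#' outside the annealing range over which chi was fitted are flagged
#' `extrapolated` (equilibrium cannot be verified there).
#'
#' @param gt_model a fitted [gordon_taylor()].
#' @param fh_model a [flory_huggins()] with chi set.
#' @param tg_points optional data frame (`x_tfd`, `tg_C`) of measured
#'   blend glass transitions.
#' @param solubility_points optional data frame (`t_anneal_C`, `x_sat`)
#'   of measured saturation points.
#' @param gt_band optional length-2 numeric (k_min, k_max), e.g. the
#'   Couchman-Karasz bounds, tabulated as `tg_lo_C`/`tg_hi_C`.
#' @param x_step composition grid step (default 0.01).
#' @param fitted_range degC annealing range inside which the solubility
#'   curve is interpolation rather than extrapolation.
#' @return An object of class `phase_diagram`: the two models, the
#'   overlay points and a `grid` data frame with columns `x_tfd`, `tg_C`,
#'   optionally `tg_lo_C`/`tg_hi_C`, `t_solubility_C`, `extrapolated`.
#' @export
build_phase_diagram <- function(gt_model, fh_model, tg_points = NULL,
                                solubility_points = NULL, gt_band = NULL,
                                x_step = 0.01,
                                fitted_range = c(120, 140)) {
  stopifnot(inherits(gt_model, "gordon_taylor"),
            inherits(fh_model, "flory_huggins"))
  if (is.na(fh_model$chi))
    stop("configuration error: fh_model has no fitted chi")
  xs <- seq(x_step, 1 - x_step, by = x_step)
  grid <- data.frame(x_tfd = xs, tg_C = gt_eval(gt_model, xs))
  if (!is.null(gt_band)) {
    lo <- gordon_taylor(gt_model$tg_drug, gt_model$tg_polymer, gt_band[1])
    hi <- gordon_taylor(gt_model$tg_drug, gt_model$tg_polymer, gt_band[2])
    grid$tg_lo_C <- pmin(gt_eval(lo, xs), gt_eval(hi, xs))
    grid$tg_hi_C <- pmax(gt_eval(lo, xs), gt_eval(hi, xs))
  }
  grid$t_solubility_C <- vapply(xs, function(x)
    suppressWarnings(solve_solubility_temperature(x, fh_model)),
    numeric(1))
  grid$extrapolated <- !is.na(grid$t_solubility_C) &
    (grid$t_solubility_C < fitted_range[1] |
     grid$t_solubility_C > fitted_range[2])
  structure(list(gt_model = gt_model, fh_model = fh_model,
                 gt_band = gt_band,
                 tg_points = tg_points,
                 solubility_points = solubility_points,
                 grid = grid),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf(
    "phase_diagram: K_GT = %.3f, chi = %.3f; grid of %d compositions\n",
    x$gt_model$k, x$fh_model$chi, nrow(x$grid)))
  invisible(x)
}

#' Classify the physical state of a composition/temperature point
#'
#' Partitions the (x, T) plane using the diagram's two curves.  Above the
#' solubility curve the polymer matrix is undersaturated and the blend is
#' a stable one-phase liquid; between the blend Tg and the solubility
#' curve the liquid is supersaturated and the excess drug tends to
#' recrystallise; below Tg the blend is glassy (and is additionally
#' flagged supersaturated when it also sits below the solubility curve,
#' the state in which kinetic arrest is the only protection).
#'
#' @param x drug weight fraction.
#' @param temperature degC.
#' @param diagram a [build_phase_diagram()] result.
#' @param boundary_tol points within this many degC of a curve are
#'   labelled `"boundary"` (default 0.05).
#' @return list with `state` (one of `"undersaturated-liquid"`,
#'   `"supersaturated-liquid"`, `"glassy"`, `"boundary"`,
#'   `"pure-component"`), `supersaturated` flag, `tg_C` and
#'   `t_solubility_C` at `x`, and for boundary points `neighbours`, the
#'   two adjacent states.
#' @examples
#' \dontrun{classify_state(0.90, 25, diagram)}
#' @export
classify_state <- function(x, temperature, diagram, boundary_tol = 0.05) {
  stopifnot(inherits(diagram, "phase_diagram"))
  if (x <= 0 || x >= 1)
    return(list(state = "pure-component", supersaturated = FALSE,
                tg_C = NA_real_, t_solubility_C = NA_real_))
  tgx <- gt_eval(diagram$gt_model, x)
  tsol <- suppressWarnings(
    solve_solubility_temperature(x, diagram$fh_model))
  below_sol <- !is.na(tsol) && temperature < tsol
  near_tg <- abs(temperature - tgx) <= boundary_tol
  near_sol <- !is.na(tsol) && abs(temperature - tsol) <= boundary_tol
  if (near_tg || near_sol) {
    nb <- if (near_tg) {
      c("glassy",
        if (below_sol || near_sol) "supersaturated-liquid"
        else "undersaturated-liquid")
    } else {
      if (temperature > tgx) c("supersaturated-liquid",
                               "undersaturated-liquid")
      else c("glassy", "glassy")
    }
    return(list(state = "boundary", supersaturated = below_sol,
                tg_C = tgx, t_solubility_C = tsol, neighbours = nb))
  }
  state <- if (temperature < tgx) "glassy"
    else if (below_sol) "supersaturated-liquid"
    else "undersaturated-liquid"
  list(state = state, supersaturated = below_sol,
       tg_C = tgx, t_solubility_C = tsol)
}

#' Export / import a phase diagram
#'
#' `write_phase_diagram` writes the tabulated curves as delimited text and
#' the model parameters as JSON (schema `diagram.v1`);
#' `read_phase_diagram` reconstructs an identical diagram from the JSON.
#'
#' @param diagram a [build_phase_diagram()] result.
#' @param table_path CSV path for the grid (columns `x_tfd`, `tg_C`,
#'   `t_solubility_C`, ...).
#' @param json_path JSON path for the model parameters.
#' @return `write_phase_diagram` returns the paths invisibly;
#'   `read_phase_diagram` returns a `phase_diagram`.
#' @export
write_phase_diagram <- function(diagram, table_path, json_path) {
  stopifnot(inherits(diagram, "phase_diagram"))
  write_numeric_csv(diagram$grid, table_path)
  gt <- diagram$gt_model; fh <- diagram$fh_model
  obj <- list(
    schema = "diagram.v1",
    gordon_taylor = list(tg_drug_C = gt$tg_drug,
                         tg_polymer_C = gt$tg_polymer,
                         k = gt$k, se_k = gt$se_k),
    gt_band = diagram$gt_band,
    flory_huggins = list(tm_C = fh$tm_C, dhm_kJ_mol = fh$dhm / 1000,
                         rho_drug = fh$rho_drug,
                         rho_polymer = fh$rho_polymer,
                         m_drug = fh$m_drug, mw_polymer = fh$mw_polymer,
                         chi = fh$chi, se_chi = fh$se_chi),
    tg_points = diagram$tg_points,
    solubility_points = diagram$solubility_points,
    x_step = diff(diagram$grid$x_tfd[1:2]))
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(table = table_path, json = json_path))
}

#' @rdname write_phase_diagram
#' @export
read_phase_diagram <- function(json_path) {
  obj <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (is.null(obj$schema) || obj$schema != "diagram.v1")
    stop("not a diagram.v1 file")
  g <- obj$gordon_taylor
  gt <- gordon_taylor(g$tg_drug_C, g$tg_polymer_C, g$k,
                      if (is.null(g$se_k)) NA_real_ else g$se_k)
  f <- obj$flory_huggins
  fh <- flory_huggins(f$tm_C, f$dhm_kJ_mol, f$rho_drug, f$rho_polymer,
                      f$m_drug, f$mw_polymer, chi = f$chi,
                      se_chi = if (is.null(f$se_chi)) NA_real_ else f$se_chi)
  build_phase_diagram(
    gt, fh,
    tg_points = as_df_or_null(obj$tg_points),
    solubility_points = as_df_or_null(obj$solubility_points),
    gt_band = obj$gt_band,
    x_step = obj$x_step)
}

as_df_or_null <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) NULL
  else as.data.frame(x)
}
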