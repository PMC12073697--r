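# Delimited-text I/O: comma or tab auto-detected, decimal point only,
# full double precision on write.

write_numeric_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]))
      out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

read_delim_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_delim(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  for (cn in required) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v) & nzchar(trimws(raw[[cn]])))
    if (length(bad))
      stop("parse error in ", path, ": non-numeric value '",
           raw[[cn]][bad[1]], "' in column ", cn,
           " at data row ", bad[1], " (file line ", bad[1] + 1L, ")")
    if (anyNA(v))
      stop("parse error in ", path, ": empty value in column ", cn,
           " at data row ", which(is.na(v))[1])
    raw[[cn]] <- v
  }
  raw
}

#' Read dielectric spectra from delimited text
#'
#' Reads one or more isotherms from a file with header
#' `temperature_C,frequency_Hz,eps_real,eps_imag` (comma or tab
#' delimited).  Rows are grouped by temperature, each group is sorted by
#' ascending frequency, and duplicated (temperature, frequency) rows are
#' rejected with the offending row number.
#'
#' @param path file path.
#' @return List of [dielectric_spectrum()], ordered by temperature.
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path) {
  req <- c("temperature_C", "frequency_Hz", "eps_real", "eps_imag")
  df <- read_delim_checked(path, req)
  key <- paste(df$temperature_C, df$frequency_Hz)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop("duplicate (temperature, frequency) row in ", path,
         ": data row ", i, " (T = ", df$temperature_C[i],
         " degC, F = ", df$frequency_Hz[i], " Hz)")
  }
  out <- lapply(split(df, df$temperature_C), function(g) {
    g <- g[order(g$frequency_Hz), ]
    dielectric_spectrum(g$temperature_C[1], g$frequency_Hz,
                        g$eps_real, g$eps_imag)
  })
  out <- out[order(as.numeric(names(out)))]
  unname(out)
}

#' Write dielectric spectra as delimited text
#'
#' @param spectra a [dielectric_spectrum()] or list of them.
#' @param path output path (CSV with the standard spectrum header).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  if (inherits(spectra, "dielectric_spectrum")) spectra <- list(spectra)
  rows <- lapply(spectra, function(sp)
    data.frame(temperature_C = sp$temperature,
               frequency_Hz = sp$frequencies,
               eps_real = sp$eps_real, eps_imag = sp$eps_imag))
  write_numeric_csv(do.call(rbind, rows), path)
}

#' Read / write thermograms as delimited text
#'
#' File schema: header `temperature_C,rev_cp_J_per_gC`, one row per
#' temperature.  `heat_flow_scale` lets raw reversible heat flow be
#' rescaled to specific heat on read.
#'
#' @param path file path.
#' @param heat_flow_scale multiplicative factor applied to the second
#'   column on read (default 1: the file already stores specific heat).
#' @return `read_thermogram`: a [thermogram()]; `write_thermogram`:
#'   `path`, invisibly.
#' @export
read_thermogram <- function(path, heat_flow_scale = 1) {
  df <- read_delim_checked(path, c("temperature_C", "rev_cp_J_per_gC"))
  df <- df[order(df$temperature_C), ]
  thermogram(df$temperature_C, df$rev_cp_J_per_gC * heat_flow_scale)
}

#' @rdname read_thermogram
#' @param tg a [thermogram()].
#' @export
write_thermogram <- function(tg, path) {
  stopifnot(inherits(tg, "thermogram"))
  write_numeric_csv(data.frame(temperature_C = tg$temperatures,
                               rev_cp_J_per_gC = tg$rev_cp), path)
}

#' Read / write relaxation-time tables
#'
#' File schema: `temperature_C,log10_tau_s,label,method`.
#'
#' @param points data frame with columns `temperature`, `log10_tau`,
#'   `label`, `method` (rbind-ed [relaxation_point()]s).
#' @param path file path.
#' @return `read_relaxation_table`: such a data frame;
#'   `write_relaxation_table`: `path`, invisibly.
#' @export
write_relaxation_table <- function(points, path) {
  write_numeric_csv(data.frame(temperature_C = points$temperature,
                               log10_tau_s = points$log10_tau,
                               label = points$label,
                               method = points$method), path)
}

#' @rdname write_relaxation_table
#' @export
read_relaxation_table <- function(path) {
  df <- read_delim_checked(path, c("temperature_C", "log10_tau_s"))
  data.frame(temperature = df$temperature_C,
             log10_tau = df$log10_tau_s,
             label = if ("label" %in% names(df)) df$label else "alpha",
             method = if ("method" %in% names(df)) df$method else "peak-pick",
             stringsAsFactors = FALSE)
}

#' Write fit results as JSON
#'
#' Serialise an HN deconvolution (`hn_fit.v1`), a VTFH fit with its
#' derived quantities (`vtfh.v1`) or a glass-transition analysis
#' (`dsc.v1`) as structured JSON.
#'
#' @param fit the object to serialise.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hn_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "hn_fit"))
  obj <- list(
    schema = "hn_fit.v1",
    eps_inf = fit$eps_inf,
    modes = lapply(fit$modes, function(m)
      list(delta_eps = m$delta_eps, tau_hn_s = m$tau_hn,
           alpha_hn = m$alpha_hn, beta_hn = m$beta_hn)),
    residual_rms = fit$residual_rms,
    window_Hz = fit$freq_window,
    target = fit$fit_target,
    converged = fit$converged,
    temperature_C = fit$temperature)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hn_fit_json
#' @param tau_ref reference time for the reported dynamic Tg, seconds.
#' @export
write_vtfh_json <- function(fit, path, tau_ref = 100) {
  stopifnot(inherits(fit, "vtfh_params"))
  tg <- tg_from_vtfh(fit, tau_ref)
  obj <- list(schema = "vtfh.v1",
              B_K = fit$B, T0_C = fit$t0,
              log_tau_inf = fit$log_tau_inf,
              se_B_K = fit$se_B, se_T0_C = fit$se_t0,
              tau_ref_s = tau_ref,
              tg_drs_C = tg,
              fragility_m = fragility_index(fit, tg))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hn_fit_json
#' @export
write_dsc_json <- function(fit, path) {
  one <- function(g) list(tg_onset_C = g$tg_onset,
                          tg_midpoint_C = g$tg_midpoint,
                          tg_end_C = g$tg_end,
                          delta_cp_J_per_gC = g$delta_cp)
  obj <- if (inherits(fit, "glass_transition"))
    list(schema = "dsc.v1", transitions = list(one(fit)))
  else if (inherits(fit, "multiple_transitions"))
    list(schema = "dsc.v1", transitions = lapply(fit, one))
  else stop("not a glass-transition result")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run an end-to-end analysis workflow
#'
#' Orchestrates the two standard workflows over files on disk and writes
#' every artefact plus a machine-readable manifest to `out_dir`:
#'
#' \describe{
#'   \item{dynamics}{spectrum file(s) -> conduction-free loss -> HN fit
#'     per isotherm -> relaxation-time table -> VTFH fit -> dynamic Tg and
#'     fragility (`relaxation_table.csv`, `vtfh.json`).}
#'   \item{diagram}{blend Tg table + annealing records -> Gordon-Taylor
#'     fit -> saturation points -> Flory-Huggins chi fit -> phase-and-state
#'     diagram (`diagram.csv`, `diagram.json`).}
#' }
#'
#' Any stage failure is recorded in the manifest (with the stages already
#' completed persisted) and re-raised as a warning; the bundle is still
#' returned so partial results remain inspectable.
#'
#' @param config a list.  Common fields: `workflow` ("dynamics" or
#'   "diagram"), `out_dir`, `seed`.  Dynamics fields: `spectra` (path),
#'   `n_modes`, `fit_target`, `freq_window`, `smoothing_window`,
#'   `log_tau_inf`.  Diagram fields: `tg_points` (path: `x_tfd,tg_C`),
#'   `anneal_records` (path: `t_anneal_C,tg_C`), `tg_drug_C`,
#'   `tg_polymer_C`, `fh_constants` (named list for [flory_huggins()]).
#' @return A list (the result bundle) with the stage outputs and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$workflow) ||
      !config$workflow %in% c("dynamics", "diagram"))
    stop("config error: workflow must be 'dynamics' or 'diagram'")
  if (is.null(config$out_dir)) stop("config error: out_dir missing")
  inputs <- switch(config$workflow,
                   dynamics = config$spectra,
                   diagram = c(config$tg_points, config$anneal_records))
  if (is.null(inputs) || !all(file.exists(inputs)))
    stop("config error: input file(s) missing: ",
         paste(inputs[!file.exists(inputs)], collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  manifest <- list(package = "asdtherm",
                   version = as.character(utils::packageVersion("asdtherm")),
                   workflow = config$workflow, seed = seed,
                   config = config[setdiff(names(config), "out_dir")],
                   stages = list())
  bundle <- list(manifest = NULL)
  note <- function(stage, status, detail = NULL) {
    manifest$stages[[stage]] <<- list(status = status, detail = detail)
  }
  run_stage <- function(stage, expr) {
    res <- tryCatch(list(ok = TRUE, value = expr),
                    error = function(e)
                      list(ok = FALSE, value = conditionMessage(e)))
    if (res$ok) note(stage, "ok")
    else note(stage, "failed", res$value)
    res
  }
  finish <- function() {
    manifest$stages <<- manifest$stages
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    bundle$manifest <<- manifest
    failed <- vapply(manifest$stages, function(s)
      identical(s$status, "failed"), logical(1))
    if (any(failed))
      warning("pipeline stage(s) failed: ",
              paste(names(manifest$stages)[failed], collapse = ", "))
    bundle
  }

  if (config$workflow == "dynamics") {
    st <- run_stage("read_spectra", read_spectra(config$spectra))
    if (!st$ok) return(finish())
    spectra <- st$value
    n_modes <- if (is.null(config$n_modes)) 1L else config$n_modes
    target <- if (is.null(config$fit_target)) "eps_der" else config$fit_target
    sw <- if (is.null(config$smoothing_window)) 5L else config$smoothing_window
    st <- run_stage("hn_fits", {
      lapply(spectra, function(sp) {
        sp <- log_derivative(sp, smoothing_window = sw)
        fit_hn(sp, n_modes = n_modes, fit_target = target,
               freq_window = config$freq_window, seed = seed)
      })
    })
    if (!st$ok) return(finish())
    fits <- st$value
    bundle$hn_fits <- fits
    st <- run_stage("relaxation_table", {
      pts <- do.call(rbind, unlist(lapply(fits, function(fit)
        lapply(seq_along(fit$modes), function(k) hn_peak_tau(fit, k))),
        recursive = FALSE))
      write_relaxation_table(pts, file.path(config$out_dir,
                                            "relaxation_table.csv"))
      pts
    })
    if (!st$ok) return(finish())
    points <- st$value
    bundle$relaxation_points <- points
    lti <- if (is.null(config$log_tau_inf)) -14 else config$log_tau_inf
    for (lbl in unique(points$label)) {
      sub <- points[points$label == lbl, ]
      st <- run_stage(paste0("vtfh_", lbl), {
        v <- fit_vtfh(sub, log_tau_inf = lti)
        write_vtfh_json(v, file.path(config$out_dir,
                                     paste0("vtfh_", lbl, ".json")))
        v
      })
      if (st$ok) bundle$vtfh[[lbl]] <- st$value
    }
    return(finish())
  }

  # diagram workflow
  st <- run_stage("read_inputs", {
    list(tg = read_delim_checked(config$tg_points, c("x_tfd", "tg_C")),
         anneal = read_delim_checked(config$anneal_records,
                                     c("t_anneal_C", "tg_C")))
  })
  if (!st$ok) return(finish())
  tg_pts <- st$value$tg; anneal <- st$value$anneal
  tgd <- if (is.null(config$tg_drug_C))
    tfd_pvp_constants$tg_drug_C else config$tg_drug_C
  tgp <- if (is.null(config$tg_polymer_C))
    tfd_pvp_constants$tg_polymer_C else config$tg_polymer_C
  st <- run_stage("gordon_taylor_fit",
                  gt_fit(tg_pts, tg_drug = tgd, tg_polymer = tgp))
  if (!st$ok) return(finish())
  gt <- st$value
  bundle$gt_model <- gt
  st <- run_stage("latreche_points", latreche_points(anneal, gt))
  if (!st$ok) return(finish())
  sat <- st$value
  bundle$solubility_points <- sat
  fhc <- if (is.null(config$fh_constants))
    tfd_pvp_constants[c("tm_C", "dhm_kJ_mol", "rho_drug", "rho_polymer",
                        "m_drug", "mw_polymer")]
    else config$fh_constants
  st <- run_stage("chi_fit", {
    fh <- do.call(flory_huggins, fhc)
    fit_chi(sat[!is.na(sat$x_sat), ], fh)
  })
  if (!st$ok) return(finish())
  fh <- st$value
  bundle$fh_model <- fh
  st <- run_stage("diagram", {
    pd <- build_phase_diagram(gt, fh, tg_points = tg_pts,
                              solubility_points = sat[, c("t_anneal_C",
                                                          "x_sat")])
    write_phase_diagram(pd, file.path(config$out_dir, "diagram.csv"),
                        file.path(config$out_dir, "diagram.json"))
    pd
  })
  if (st$ok) bundle$diagram <- st$value
  finish()
}
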