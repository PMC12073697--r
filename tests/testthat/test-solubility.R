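# Flory-Huggins solubility, the annealing/Tg readback, state
# classification and the assembled phase diagram.

test_that("volume fraction and molar volume ratio match hand arithmetic", {
  fh <- tfd_pvp_fh()
  expect_equal(volume_fraction(0, fh), 0)
  expect_equal(volume_fraction(1, fh), 1)
  expect_true(all(diff(volume_fraction(seq(0, 1, 0.05), fh)) > 0))
  # x = 0.66 with rho 1.05/1.17
  expect_equal(volume_fraction(0.66, fh),
               (0.66 / 1.05) / (0.66 / 1.05 + 0.34 / 1.17),
               tolerance = 1e-12)
  expect_equal(volume_fraction(0.66, fh), 0.684, tolerance = 1e-3)
  # equal densities make phi the identity
  same <- flory_huggins(150, 54.2, 1.1, 1.1, 471.7, 2500)
  expect_equal(volume_fraction(0.37, same), 0.37, tolerance = 1e-12)
  # lambda = Mw rho_d / (rho_p M_d), linear in the polymer mass
  expect_equal(lambda_ratio(fh), 2500 * 1.05 / (1.17 * 471.7),
               tolerance = 1e-12)
  expect_equal(lambda_ratio(fh), 4.76, tolerance = 1e-3)
  expect_equal(lambda_ratio(same), 2500 / 471.7, tolerance = 1e-12)
  dbl <- flory_huggins(150, 54.2, 1.05, 1.17, 471.7, 5000)
  expect_equal(lambda_ratio(dbl), 2 * lambda_ratio(fh), tolerance = 1e-12)
})

test_that("the melting point anchors the residual and chi enters linearly", {
  fh <- tfd_pvp_fh(chi = -2.3)
  expect_equal(fh_residual(1, 150, fh), 0)
  expect_error(fh_residual(0, 140, fh), "> 0")
  # residual is affine in chi with slope -(1 - phi)^2
  phi <- volume_fraction(0.66, fh)
  r1 <- fh_residual(0.66, 140, fh, chi = -1)
  r2 <- fh_residual(0.66, 140, fh, chi = -3)
  expect_equal((r2 - r1) / 2, (1 - phi)^2, tolerance = 1e-12)
  # near the fitted liquidus the residual is small
  expect_lt(abs(fh_residual(0.66, 140, fh)), 0.05)
})

test_that("solubility temperatures anchor at Tm and decrease with dilution", {
  fh <- tfd_pvp_fh(chi = -2.3)
  expect_equal(solve_solubility_temperature(0.999, fh), 150,
               tolerance = 0.1 / 150)
  ts <- vapply(c(0.9, 0.7, 0.5, 0.3), solve_solubility_temperature,
               numeric(1), model = fh)
  expect_true(all(diff(ts) < 0))
  # brute-force residual grid agrees with the root
  t66 <- solve_solubility_temperature(0.66, fh)
  grid <- seq(50, 200, by = 0.01)
  gi <- which.min(abs(fh_residual(0.66, grid, fh)))
  expect_equal(t66, grid[gi], tolerance = 0.02 / 140)
  expect_equal(t66, 140, tolerance = 2 / 140)
  # a bracket with no sign change reports no solution
  expect_warning(
    expect_true(is.na(solve_solubility_temperature(
      0.5, fh, bracket = c(145, 150)))),
    "no solubility solution")
})

test_that("chi fitted to the annealing table matches the published value", {
  fit <- fit_chi(tfd_pvp_solubility, tfd_pvp_fh())
  expect_equal(fit$chi, -2.3, tolerance = 0.15 / 2.3)
  expect_true(is.finite(fit$se_chi) && fit$se_chi > 0)
  # the closed form equals a brute-force 1-d minimisation
  obj <- function(chi) sum(fh_residual(tfd_pvp_solubility$x_sat,
                                       tfd_pvp_solubility$t_anneal_C,
                                       tfd_pvp_fh(), chi = chi)^2)
  brute <- stats::optimize(obj, c(-10, 5), tol = 1e-12)$minimum
  expect_equal(fit$chi, brute, tolerance = 1e-7)
})

test_that("chi fitting is exact on self-generated points and per-point
           solutions bracket the joint fit", {
  fh <- tfd_pvp_fh(chi = -5)
  xs <- c(0.3, 0.45, 0.6, 0.75)
  ts <- vapply(xs, solve_solubility_temperature, numeric(1), model = fh)
  fit <- fit_chi(data.frame(t_anneal_C = ts, x_sat = xs), tfd_pvp_fh())
  expect_equal(fit$chi, -5, tolerance = 1e-9)
  # per-point chi values on the annealing table
  fh0 <- tfd_pvp_fh()
  phi <- volume_fraction(tfd_pvp_solubility$x_sat, fh0)
  chis <- fh_residual(tfd_pvp_solubility$x_sat,
                      tfd_pvp_solubility$t_anneal_C, fh0, chi = 0) /
    (1 - phi)^2
  expect_gt(min(chis), -2.7)
  expect_lt(max(chis), -1.9)
  joint <- fit_chi(tfd_pvp_solubility, fh0)$chi
  expect_gt(joint, min(chis))
  expect_lt(joint, max(chis))
})

test_that("the Tg readback converts annealing records to saturation points", {
  gt <- gordon_taylor(60, 106, 0.76)
  out <- latreche_points(data.frame(t_anneal_C = c(140, 130),
                                    tg_C = c(73, 81)), gt)
  expect_equal(out$t_anneal_C, c(130, 140))          # ordered by T_a
  expect_equal(out$x_sat[out$t_anneal_C == 140], 0.66, tolerance = 0.015)
  expect_equal(out$x_sat[out$t_anneal_C == 130], 0.48, tolerance = 0.025)
  # an endpoint Tg yields an error entry while others are processed
  out2 <- latreche_points(data.frame(t_anneal_C = c(120, 140),
                                     tg_C = c(106, 73)), gt)
  expect_true(is.na(out2$x_sat[1]) && !is.na(out2$error[1]))
  expect_false(is.na(out2$x_sat[2]))
  # round trip: x -> Tg -> x is the identity
  xs <- seq(0.1, 0.9, 0.1)
  rt <- latreche_points(data.frame(t_anneal_C = seq_along(xs),
                                   tg_C = gt_eval(gt, xs)), gt)
  expect_equal(sort(rt$x_sat), sort(xs), tolerance = 1e-10)
})

test_that("the state classifier partitions the composition-temperature plane", {
  gt <- gt_fit(data.frame(x_tfd = tfd_pvp_tg$x_tfd,
                          tg_C = tfd_pvp_tg$tg_midpoint_C))
  fh <- fit_chi(tfd_pvp_solubility, tfd_pvp_fh())
  pd <- build_phase_diagram(gt, fh)
  # hot, dilute-in-polymer liquid above the liquidus
  expect_equal(classify_state(0.66, 145, pd)$state, "undersaturated-liquid")
  # a room-temperature co-milled dispersion: glassy and supersaturated
  cs <- classify_state(0.90, 25, pd)
  expect_equal(cs$state, "glassy")
  expect_true(cs$supersaturated)
  # between Tg and the liquidus the liquid is supersaturated
  cs2 <- classify_state(0.66, 100, pd)
  expect_equal(cs2$state, "supersaturated-liquid")
  # pure components and boundary points
  expect_equal(classify_state(0, 25, pd)$state, "pure-component")
  tgx <- gt_eval(gt, 0.5)
  bd <- classify_state(0.5, tgx, pd)
  expect_equal(bd$state, "boundary")
  expect_length(bd$neighbours, 2L)
  # every off-boundary point gets exactly one primary label
  withr::with_seed(19, {
    for (k in 1:40) {
      x <- runif(1, 0.05, 0.95); tc <- runif(1, 0, 200)
      st <- classify_state(x, tc, pd)
      expect_true(st$state %in% c("undersaturated-liquid",
                                  "supersaturated-liquid",
                                  "glassy", "boundary"))
    }
  })
})

test_that("the assembled diagram round-trips and is internally consistent", {
  gt <- gordon_taylor(60, 106, 0.76, se_k = 0.02)
  fh <- fit_chi(tfd_pvp_solubility, tfd_pvp_fh())
  pd <- build_phase_diagram(gt, fh, gt_band = c(0.56, 0.66),
                            tg_points = data.frame(
                              x_tfd = tfd_pvp_tg$x_tfd,
                              tg_C = tfd_pvp_tg$tg_midpoint_C),
                            solubility_points = tfd_pvp_solubility[
                              c("t_anneal_C", "x_sat")])
  expect_true(all(diff(pd$grid$x_tfd) > 0))
  # the state and solubility curves cross exactly once
  dd <- pd$grid$t_solubility_C - pd$grid$tg_C
  dd <- dd[is.finite(dd)]
  expect_equal(sum(diff(sign(dd)) != 0), 1L)
  # extrapolation flagged outside the annealing window
  expect_true(any(pd$grid$extrapolated))
  fitted <- pd$grid$t_solubility_C >= 120 & pd$grid$t_solubility_C <= 140
  expect_true(all(!pd$grid$extrapolated[fitted], na.rm = TRUE))
  # export/import identity
  tf <- withr::local_tempfile(fileext = ".csv")
  jf <- withr::local_tempfile(fileext = ".json")
  write_phase_diagram(pd, tf, jf)
  pd2 <- read_phase_diagram(jf)
  expect_equal(pd2$grid, pd$grid, tolerance = 1e-12)
  expect_equal(pd2$gt_model$k, pd$gt_model$k)
  expect_equal(pd2$fh_model$chi, pd$fh_model$chi)
  # unfitted chi is a configuration error
  expect_error(build_phase_diagram(gt, tfd_pvp_fh()), "chi")
})
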