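# mixed-layer box model: TA slaving, NCP conversion, stepping, trajectories

test_that("TA follows salinity linearly and is anchored at S = 35", {
  p <- box_params("nwa")
  expect_equal(ta_from_salinity(35, p), 2280)
  s <- seq(28, 37, by = 0.5)
  ta <- ta_from_salinity(s, p)
  expect_equal(diff(ta), rep(p$ta_slope * 0.5, length(s) - 1))
  expect_true(all(diff(ta) > 0))
  # region presets differ only via mixing; TA anchoring is shared
  expect_equal(ta_from_salinity(33, box_params("sab")),
               ta_from_salinity(33, p))
  expect_error(ta_from_salinity(-1, p), "salinity")
})

test_that("chlorophyll-to-NCP conversion has the documented arithmetic", {
  expect_true(all(chl_to_ncp(rep(1.3, 30)) == 0))
  # a bloom rising 0.1 mg/m3/day for a week: NCP = 0.1*60/12 = 0.5
  chl <- c(rep(1, 8), 1 + 0.1 * (1:7), rep(1.7, 8))
  ncp <- chl_to_ncp(chl, 60)
  expect_equal(max(ncp), 0.5, tolerance = 1e-9)
  # all-gap week: zero NCP with a warning
  chl_gap <- c(rep(1, 8), rep(NA, 8), rep(1, 7))
  expect_warning(ncp_gap <- chl_to_ncp(chl_gap), "all-gap")
  expect_true(all(is.finite(ncp_gap)))
  expect_error(chl_to_ncp(c(1, -0.5, 1)), "non-negative")
})

test_that("a single step honours its trivial limits", {
  p <- box_params("nwa")
  eq <- carb_solve_pco2(p$pco2_atm, 2280, 15, 35)
  calm <- data.frame(wind_ms = 0, ncp_mmol_m3_d = 0, mix_mmol_m3_d = 0)
  s1 <- box_step(eq, calm, p)
  expect_equal(unname(s1$increments), c(0, 0, 0))
  expect_equal(s1$state$dic, eq$dic)
  # at equilibrium even with wind the increments vanish
  windy <- data.frame(wind_ms = 8, ncp_mmol_m3_d = 0, mix_mmol_m3_d = 0)
  expect_equal(unname(box_step(eq, windy, p)$increments), c(0, 0, 0))
  # supersaturated water outgasses: DIC strictly decreases
  sup <- carb_solve(eq$dic + 30, 2280, 15, 35)
  s2 <- box_step(sup, windy, p)
  expect_lt(s2$state$dic, sup$dic)
  expect_lt(s2$increments[["airsea"]], 0)
})

nwa_forcing <- make_forcing("nwa", 365, seed = 1)
nwa_traj <- box_run(nwa_forcing, box_params("nwa"))

test_that("per-step DIC budget closes exactly and TA only follows salinity", {
  tr <- nwa_traj
  resid <- diff(tr$dic) -
    (tr$flux_airsea + tr$flux_bio + tr$flux_mix)[-nrow(tr)]
  expect_lt(max(abs(resid)), 1e-9)
  expect_equal(tr$ta, ta_from_salinity(tr$sss, box_params("nwa")))
})

test_that("NWA seasonal run phases as the cold-margin framework predicts", {
  tr <- nwa_traj
  winter <- tr$day[which.max(tr$dic)]
  expect_true(winter >= 335 || winter <= 95)       # DIC max in winter
  om_min <- tr$day[which.min(tr$omega_arag)]
  expect_true(om_min >= 335 || om_min <= 95)       # omega min in winter
  spring <- tr$day %in% 80:120; summer <- tr$day %in% 190:230
  expect_gt(mean(tr$pco2_uatm[summer]), mean(tr$pco2_uatm[spring]))
  expect_lt(mean(tr$ph_total[summer]), mean(tr$ph_total[spring]))
})

test_that("modeled DIC lags the instantaneous-equilibrium series by 1-2 months", {
  tr <- nwa_traj
  lags <- 0:90
  cc <- vapply(lags, function(L)
    cor(tr$dic[(L + 1):nrow(tr)], tr$dic_eq[1:(nrow(tr) - L)]), numeric(1))
  best <- lags[which.max(cc)]
  expect_gte(best, 30)
  expect_lte(best, 60)
})

test_that("the instantaneous-equilibrium wind limit collapses DIC onto DIC_eq", {
  fc <- nwa_forcing
  fc$wind_ms <- fc$wind_ms * 100
  tr <- box_run(fc, box_params("nwa"))
  expect_lt(max(abs(tr$dic - tr$dic_eq)), 2)
})

test_that("warm SAB box is less acidified than the cold NWA box year-round", {
  trs <- box_run(make_forcing("sab", 365, seed = 1), box_params("sab"))
  expect_true(all(trs$dic / trs$ta < nwa_traj$dic / nwa_traj$ta))
  expect_true(all(trs$omega_arag > nwa_traj$omega_arag))
})

test_that("forcing shorter than the spin-up is rejected", {
  p <- box_params("nwa")
  expect_error(box_run(nwa_forcing[1:100, ], p), "shorter than spin-up")
  expect_error(box_run(nwa_forcing[, 1:3], p), "lacks columns")
})

test_that("e-folding time decays with wind, scales with depth, is exponential", {
  p <- box_params("nwa")
  taus <- vapply(c(4, 7, 10.5), function(w)
    efolding_time(p, dic_pulse = 20, wind = w, horizon = 900), numeric(1))
  expect_true(all(diff(taus) < 0))
  # closed-system limit: no decay within the horizon
  expect_error(efolding_time(p, wind = 0, horizon = 50), "not decaying")
  expect_error(efolding_time(p, wind = 0.5, horizon = 60), "horizon")
  # doubling the mixed layer doubles tau (within 15%)
  t20 <- efolding_time(p, wind = 7)
  t40 <- efolding_time(box_params("nwa", mld_m = 40), wind = 7, horizon = 900)
  expect_equal(t40 / t20, 2, tolerance = 0.15)
  # small-pulse decay is a clean single exponential
  ta <- ta_from_salinity(35, p)
  st <- carb_solve(carb_solve_pco2(395, ta, 15, 35)$dic + 5, ta, 15, 35)
  fday <- data.frame(wind_ms = 7, ncp_mmol_m3_d = 0, mix_mmol_m3_d = 0)
  ex <- numeric(100)
  for (i in seq_along(ex)) {
    st <- box_step(st, fday, p)$state
    ex[i] <- st$pco2 - 395
  }
  fit <- stats::lm(log(ex) ~ seq_along(ex))
  expect_gt(summary(fit)$r.squared, 0.99)
})
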