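# Daily mixed-layer box model of the surface-ocean CO2 system.
#
# State: DIC (umol kg-1) in a homogeneous box of depth mld_m; TA is slaved
# to prescribed salinity and never responds to fluxes. Each day the box
# exchanges CO2 with a fixed atmosphere, loses DIC to net community
# production and gains DIC from vertical winter mixing:
#   DIC[t+1] = DIC[t] + dDIC_airsea + dDIC_bio + dDIC_mix.

#' Box-model parameters
#'
#' Bundles the tunable parameters of the mixed-layer simulation. Region
#' presets differ only in the winter-mixing rate (0.1 mmol m-3 day-1 over
#' the 155-day October-February window in the cold north-west Atlantic
#' preset `"nwa"`; none in the warm South Atlantic Bight preset `"sab"`);
#' both share the same TA-salinity anchoring (2280 umol kg-1 at S = 35).
#'
#' @param region `"nwa"` or `"sab"`.
#' @param ta_slope,ta_intercept linear TA(S) coefficients, umol kg-1 per
#'   salinity unit and umol kg-1.
#' @param pco2_atm atmospheric pCO2, uatm (seasonally invariant).
#' @param mld_m mixed-layer depth, m; converts the per-area flux law to a
#'   per-volume DIC tendency. The value is an explicit modelling choice,
#'   not observationally fixed.
#' @param rho_kg_m3 seawater density for umol kg-1 <-> mmol m-3
#'   conversions.
#' @param c_to_chl carbon-to-chlorophyll mass ratio, g g-1.
#' @param spinup_days spin-up length, days, discarded from outputs.
#' @param mixing_rate winter vertical mixing DIC source, mmol m-3 day-1.
#' @param opts a [carb_options()] configuration.
#' @return list of class `"box_params"`.
#' @export
box_params <- function(region = c("nwa", "sab"),
                       ta_slope = 50, ta_intercept = 530,
                       pco2_atm = 395, mld_m = 20, rho_kg_m3 = 1025,
                       c_to_chl = 60, spinup_days = 180,
                       mixing_rate = NULL, opts = carb_options()) {
  region <- match.arg(region)
  if (is.null(mixing_rate))
    mixing_rate <- if (region == "nwa") 0.1 else 0
  stopifnot(mld_m > 0, spinup_days >= 0, rho_kg_m3 > 0)
  structure(list(region = region, ta_slope = ta_slope,
                 ta_intercept = ta_intercept, pco2_atm = pco2_atm,
                 mld_m = mld_m, rho_kg_m3 = rho_kg_m3,
                 c_to_chl = c_to_chl, spinup_days = spinup_days,
                 mixing_rate = mixing_rate, opts = opts),
            class = "box_params")
}

#' Total alkalinity from salinity
#'
#' Linear TA(S) relation used throughout the box model; the defaults are
#' anchored so S = 35 gives 2280 umol kg-1.
#'
#' @param salinity practical salinity (> 0); vectorised.
#' @param params a [box_params()] object.
#' @return TA, umol kg-1.
#' @export
ta_from_salinity <- function(salinity, params = box_params()) {
  if (any(salinity <= 0)) stop("salinity must be positive")
  params$ta_slope * salinity + params$ta_intercept
}

#' Net community production from a chlorophyll series
#'
#' Converts day-to-day changes of chlorophyll (mg m-3) into a net DIC sink
#' (mmol C m-3 day-1) with a fixed C:Chl mass ratio: daily differences over
#' valid consecutive-day pairs are averaged by week, multiplied by
#' `c_to_chl`/12 (mg C per mg Chl, then to mmol C), and interpolated back
#' to a daily series. Positive NCP removes DIC.
#'
#' @param chl daily chlorophyll, mg m-3; `NA` marks gaps.
#' @param c_to_chl carbon-to-chlorophyll mass ratio, g g-1.
#' @return daily NCP, mmol C m-3 day-1, same length as `chl`.
#' @export
#' @examples
#' chl_to_ncp(c(rep(1, 4), 1 + 0.1 * (1:10)))  # a 0.1 mg/m3/day bloom
chl_to_ncp <- function(chl, c_to_chl = 60) {
  if (any(chl < 0, na.rm = TRUE)) stop("chlorophyll must be non-negative")
  n <- length(chl)
  if (n < 2) return(rep(0, n))
  dchl <- diff(chl)                       # NA where either day missing
  week <- (seq_along(dchl) - 1) %/% 7
  wk_mean <- tapply(dchl, week, function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  if (anyNA(wk_mean)) {
    warning(sum(is.na(wk_mean)), " all-gap week(s); NCP set to 0 there")
    wk_mean[is.na(wk_mean)] <- 0
  }
  # weekly value anchored at the middle day of each week (integer day so
  # the weekly average is attained exactly on the daily series)
  wk_mid <- tapply(seq_along(dchl), week, function(ix) ceiling(mean(ix)))
  ncp_wk <- as.numeric(wk_mean) * c_to_chl / 12
  if (length(ncp_wk) == 1L) return(rep(ncp_wk, n))
  stats::approx(as.numeric(wk_mid), ncp_wk, xout = seq_len(n), rule = 2)$y
}

# umol kg-1 per (mmol m-3): 1000 / rho
.vol_to_mass <- function(params) 1000 / params$rho_kg_m3

#' One daily step of the box model
#'
#' Implements the forward iteration: the gas-exchange increment is computed
#' from the pCO2 of the incoming state, biological and mixing increments
#' are taken from the forcing, DIC is updated, and the carbonate system is
#' recalculated with the temperature, salinity and TA of the incoming day
#' (so all carbon parameters refer to the same physical conditions);
#' temperature, salinity and TA advance at the start of the next step.
#'
#' The air-sea increment integrates the linearised gas-exchange relaxation
#' over the day in closed form,
#' \eqn{\Delta DIC = -(\Delta pCO_2/s)(1 - e^{-\lambda})} with
#' \eqn{s = \partial pCO_2/\partial DIC} and \eqn{\lambda = a s} the daily
#' relaxation rate implied by the flux law. For the wind speeds of
#' interest (\eqn{\lambda \ll 1}) this equals the plain explicit increment
#' \eqn{-a\,\Delta pCO_2} to second order; unlike the explicit form it
#' stays stable in the instantaneous-equilibrium limit (very large winds),
#' where it relaxes DIC to its atmospheric-equilibrium value within the
#' day instead of overshooting.
#'
#' @param state a solved single-row `"carb_state"` at day t.
#' @param forcing_day one-row data.frame with `wind_ms`, `ncp_mmol_m3_d`
#'   (DIC sink positive) and `mix_mmol_m3_d` (DIC source positive).
#' @param params a [box_params()] object.
#' @return list: `state` (recalculated `"carb_state"` with the new DIC at
#'   the old physical conditions) and `increments` (named vector
#'   `airsea, bio, mix`, umol kg-1 day-1; `airsea` > 0 means uptake).
#' @export
box_step <- function(state, forcing_day, params = box_params()) {
  stopifnot(inherits(state, "carb_state"), nrow(state) == 1L)
  v2m <- .vol_to_mass(params)
  k <- carb_constants(state$temperature, state$salinity, params$opts)
  kv <- gas_transfer_velocity(forcing_day$wind_ms,
                              schmidt_number(state$temperature))
  a <- 0.24 * kv * k$K0 / params$mld_m * v2m   # umol kg-1 d-1 per uatm
  dp <- state$pco2 - params$pco2_atm
  if (a == 0 || dp == 0) {
    airsea <- 0
  } else {
    # local pCO2 sensitivity to DIC at fixed T, S, TA (uatm per umol kg-1)
    pert <- carb_solve(state$dic + c(-0.5, 0.5), state$ta,
                       state$temperature, state$salinity,
                       opts = params$opts)
    s <- diff(pert$pco2)
    lambda <- a * s
    airsea <- -(dp / s) * (1 - exp(-lambda))
  }
  inc <- c(airsea = airsea,
           bio = -forcing_day$ncp_mmol_m3_d * v2m,
           mix = forcing_day$mix_mmol_m3_d * v2m)
  dic_next <- state$dic + inc[["airsea"]] + inc[["bio"]] + inc[["mix"]]
  st <- tryCatch(
    carb_solve(dic_next, state$ta, state$temperature, state$salinity,
               opts = params$opts),
    error = function(e) stop("box step failed: ", conditionMessage(e)))
  list(state = st, increments = inc)
}

#' Run the box model over a forcing series
#'
#' The run is initialised at the first spin-up day with TA from salinity
#' and DIC at equilibrium with the atmosphere, spun up for
#' `params$spinup_days` days by replaying the forcing days that precede
#' day 1 in the (periodic) first year, and then integrated over the full
#' forcing. Each reported day records the state at the start of the day
#' (its own temperature, salinity and TA), the three DIC increments
#' applied during the day, and the instantaneous-equilibrium companion
#' `dic_eq` (same TA, salinity and temperature, pCO2 relaxed to the
#' atmosphere: infinitely fast gas exchange).
#'
#' @param forcing data.frame with columns `day, sst_c, sss, wind_ms,
#'   ncp_mmol_m3_d, mix_mmol_m3_d` (see [make_forcing()]); at least
#'   `params$spinup_days` rows.
#' @param params a [box_params()] object.
#' @return data.frame of class `"box_trajectory"`: `day, sst_c, sss, ta,
#'   dic, ph_total, pco2_uatm, omega_arag, dic_eq, flux_airsea, flux_bio,
#'   flux_mix` (flux columns are the umol kg-1 increments applied during
#'   that day; `dic[t+1] - dic[t]` equals their sum exactly).
#' @export
box_run <- function(forcing, params = box_params()) {
  need <- c("day", "sst_c", "sss", "wind_ms", "ncp_mmol_m3_d", "mix_mmol_m3_d")
  miss <- setdiff(need, names(forcing))
  if (length(miss)) stop("forcing lacks columns: ", paste(miss, collapse = ", "))
  n <- nrow(forcing)
  if (n < params$spinup_days)
    stop("forcing (", n, " days) shorter than spin-up (",
         params$spinup_days, " days)")
  nsp <- params$spinup_days
  year1 <- min(365L, n)
  # the spin-up replays the forcing days that cyclically precede day 1
  spin_idx <- if (nsp > 0)
    ((seq(year1 - nsp, year1 - 1) %% year1) + 1L) else integer(0)
  full <- rbind(forcing[spin_idx, , drop = FALSE], forcing)
  ndays <- nrow(full)

  ta0 <- ta_from_salinity(full$sss[1], params)
  state <- carb_solve_pco2(params$pco2_atm, ta0, full$sst_c[1], full$sss[1],
                           opts = params$opts)
  rows <- vector("list", ndays)
  for (i in seq_len(ndays)) {
    ta_i <- ta_from_salinity(full$sss[i], params)
    # advance T, S, TA at the start of the step; DIC carries over
    state <- carb_solve(state$dic, ta_i, full$sst_c[i], full$sss[i],
                        opts = params$opts)
    eq <- carb_solve_pco2(params$pco2_atm, ta_i, full$sst_c[i], full$sss[i],
                          opts = params$opts)
    stp <- tryCatch(box_step(state, full[i, ], params),
                    error = function(e)
                      stop("day ", full$day[i], ": ", conditionMessage(e)))
    rows[[i]] <- data.frame(
      day = full$day[i], sst_c = full$sst_c[i], sss = full$sss[i],
      ta = ta_i, dic = state$dic, ph_total = state$ph,
      pco2_uatm = state$pco2, omega_arag = state$omega_arag,
      dic_eq = eq$dic,
      flux_airsea = stp$increments[["airsea"]],
      flux_bio = stp$increments[["bio"]],
      flux_mix = stp$increments[["mix"]])
    state <- stp$state
  }
  out <- do.call(rbind, rows[(nsp + 1):ndays])
  rownames(out) <- NULL
  structure(out, class = c("box_trajectory", "data.frame"))
}

#' e-folding time of a DIC disturbance
#'
#' Starts the box at steady state (pCO2 equal to the atmosphere, no
#' biology or mixing, constant temperature, salinity and wind), adds a
#' one-day DIC pulse, and integrates gas exchange alone until the excess
#' pCO2 has decayed to 1/e of its initial value; the crossing day is
#' refined by linear interpolation between daily samples.
#'
#' @param params a [box_params()] object.
#' @param dic_pulse pulse size, umol kg-1 (> 0).
#' @param wind constant wind speed, m s-1.
#' @param temperature,salinity constant box conditions.
#' @param horizon maximum days to integrate.
#' @return e-folding time in days.
#' @export
efolding_time <- function(params = box_params(), dic_pulse = 20, wind = 7,
                          temperature = 15, salinity = 35, horizon = 400) {
  stopifnot(dic_pulse > 0, wind >= 0, horizon >= 2)
  ta <- ta_from_salinity(salinity, params)
  base <- carb_solve_pco2(params$pco2_atm, ta, temperature, salinity,
                          opts = params$opts)
  state <- carb_solve(base$dic + dic_pulse, ta, temperature, salinity,
                      opts = params$opts)
  ex0 <- state$pco2 - params$pco2_atm
  target <- ex0 / exp(1)
  forcing_day <- data.frame(wind_ms = wind, ncp_mmol_m3_d = 0,
                            mix_mmol_m3_d = 0)
  ex_prev <- ex0
  for (d in seq_len(horizon)) {
    state <- box_step(state, forcing_day, params)$state
    ex <- state$pco2 - params$pco2_atm
    if (ex <= target) {
      # linear interpolation between day d-1 (ex_prev) and day d (ex)
      return((d - 1) + (ex_prev - target) / (ex_prev - ex))
    }
    if (ex >= ex_prev)
      stop("excess pCO2 is not decaying (wind too low?)")
    ex_prev <- ex
  }
  stop("excess pCO2 did not reach 1/e within the ", horizon, "-day horizon")
}
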