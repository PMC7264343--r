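# Air-sea CO2 exchange and atmospheric-equilibrium predictions.

#' Schmidt number for CO2 in seawater
#'
#' Fourth-order polynomial in temperature (Wanninkhof 2014), fitted for
#' salinity 35; the `salinity` argument is accepted for interface
#' uniformity but the polynomial carries no salinity dependence.
#'
#' @param temperature degrees C, in \[-2, 40\]; vectorised.
#' @param salinity nominal salinity (unused by the polynomial).
#' @return dimensionless Schmidt number (about 660 at 20 degrees C).
#' @export
schmidt_number <- function(temperature, salinity = 35) {
  if (any(!is.finite(temperature) | temperature < -2 | temperature > 40))
    stop("temperature out of range [-2, 40]")
  t <- temperature
  2116.8 - 136.25 * t + 4.7353 * t^2 - 0.092307 * t^3 + 0.0007555 * t^4
}

#' Gas-transfer (piston) velocity
#'
#' \eqn{k = 0.251\, W^2 (Sc/660)^{-0.5}} in cm h-1, quadratic in wind
#' speed, normalised to the Schmidt number of CO2 at 20 degrees C in
#' seawater (660).
#'
#' @param wind wind speed at 10 m, m s-1 (>= 0); vectorised.
#' @param sc Schmidt number (> 0).
#' @return transfer velocity, cm h-1.
#' @export
#' @examples
#' gas_transfer_velocity(7, 660)  # 0.251 * 49 = 12.299
gas_transfer_velocity <- function(wind, sc) {
  if (any(wind < 0)) stop("wind speed must be non-negative")
  if (any(sc <= 0)) stop("Schmidt number must be positive")
  0.251 * wind^2 * (sc / 660)^-0.5
}

#' Air-sea CO2 flux
#'
#' \eqn{F = 0.24\, k\, K_0\, (pCO_{2,aq} - pCO_{2,atm})} in
#' mmol m-2 day-1; 0.24 converts the transfer velocity from cm h-1 to
#' m day-1, and K0 (mol kg-1 atm-1) times the uatm pressure difference is
#' read as mmol m-3 (the conventional seawater-density shortcut of the
#' flux law). Positive flux is ocean-to-atmosphere efflux.
#'
#' @param state a solved `"carb_state"` data.frame (vectorised over rows).
#' @param pco2_atm atmospheric pCO2, uatm.
#' @param wind wind speed, m s-1.
#' @param opts a [carb_options()] configuration.
#' @return flux, mmol m-2 day-1.
#' @export
co2_flux <- function(state, pco2_atm, wind, opts = carb_options()) {
  stopifnot(inherits(state, "carb_state"))
  vapply(seq_len(nrow(state)), function(i) {
    k <- carb_constants(state$temperature[i], state$salinity[i], opts)
    kv <- gas_transfer_velocity(wind, schmidt_number(state$temperature[i]))
    0.24 * kv * k$K0 * (state$pco2[i] - pco2_atm)
  }, numeric(1))
}

#' State at equilibrium with atmospheric pCO2
#'
#' Solves the CO2 system from TA and the atmospheric pCO2, the prediction
#' of DIC, Omega_arag, pH and pCO2 if air-sea exchange were complete.
#'
#' @param ta total alkalinity, umol kg-1; vectorised with the conditions.
#' @param temperature,salinity in-situ conditions.
#' @param pco2_atm atmospheric pCO2, uatm.
#' @param phosphate,silicate nutrient totals, umol kg-1.
#' @param opts a [carb_options()] configuration.
#' @return A `"carb_state"` data.frame.
#' @export
equilibrium_state <- function(ta, temperature, salinity, pco2_atm = 395,
                              phosphate = 0, silicate = 0,
                              opts = carb_options()) {
  carb_solve_pco2(pco2_atm, ta, temperature, salinity,
                  phosphate, silicate, opts = opts)
}

#' Observed vs atmospheric-equilibrium deviation analysis
#'
#' For each transect sample, solves the observed state from (DIC, TA) and
#' the equilibrium state from (pCO2_atm, TA) at the same temperature and
#' salinity, tabulates the deviations (observed minus equilibrium) of DIC,
#' Omega_arag, pH and pCO2, and reports the Pearson correlations of the
#' DIC, Omega and pH deviations with the air-sea pCO2 difference.
#'
#' Rows lacking TA or DIC are dropped with a message. With fewer than 3
#' complete rows, or a zero-variance deviation column, the corresponding
#' correlation is `NA`.
#'
#' @param transect a `"transect"` data.frame (see [make_transect()] /
#'   [read_bottle_csv()]) with columns `sst_c, sss, ta_umol_kg,
#'   dic_umol_kg` (nutrient columns used when present).
#' @param pco2_atm atmospheric pCO2, uatm.
#' @param opts a [carb_options()] configuration.
#' @return list with `table` (per-sample observed, equilibrium and
#'   deviation columns plus carried covariates) and `correlations` (named
#'   vector: `r_dic`, `r_omega`, `r_ph` against `d_pco2`).
#' @export
deviation_analysis <- function(transect, pco2_atm = 395,
                               opts = carb_options()) {
  need <- c("sst_c", "sss", "ta_umol_kg", "dic_umol_kg")
  miss <- setdiff(need, names(transect))
  if (length(miss)) stop("transect lacks columns: ", paste(miss, collapse = ", "))
  ok <- stats::complete.cases(transect[need])
  if (any(!ok))
    message(sum(!ok), " row(s) without TA/DIC/SST/SSS excluded from speciation")
  tr <- transect[ok, , drop = FALSE]
  po4 <- if ("po4_umol_kg" %in% names(tr))
    ifelse(is.na(tr$po4_umol_kg), 0, tr$po4_umol_kg) else 0
  sio4 <- if ("sio4_umol_kg" %in% names(tr))
    ifelse(is.na(tr$sio4_umol_kg), 0, tr$sio4_umol_kg) else 0
  obs <- carb_solve(tr$dic_umol_kg, tr$ta_umol_kg, tr$sst_c, tr$sss,
                    po4, sio4, opts)
  eq <- equilibrium_state(tr$ta_umol_kg, tr$sst_c, tr$sss, pco2_atm,
                          po4, sio4, opts)
  tab <- data.frame(
    sst_c = tr$sst_c, sss = tr$sss, ta_umol_kg = tr$ta_umol_kg,
    dic_obs = obs$dic, dic_eq = eq$dic,
    omega_obs = obs$omega_arag, omega_eq = eq$omega_arag,
    ph_obs = obs$ph, ph_eq = eq$ph,
    pco2_obs = obs$pco2, pco2_eq = eq$pco2)
  tab$d_dic <- tab$dic_obs - tab$dic_eq
  tab$d_omega <- tab$omega_obs - tab$omega_eq
  tab$d_ph <- tab$ph_obs - tab$ph_eq
  tab$d_pco2 <- tab$pco2_obs - pco2_atm
  for (cv in c("no3_umol_kg", "do_percent", "label"))
    if (cv %in% names(tr)) tab[[cv]] <- tr[[cv]]
  safe_cor <- function(x, y) {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(NA_real_)
    stats::cor(x, y, use = "pairwise.complete.obs")
  }
  list(table = tab,
       correlations = c(r_dic = safe_cor(tab$d_dic, tab$d_pco2),
                        r_omega = safe_cor(tab$d_omega, tab$d_pco2),
                        r_ph = safe_cor(tab$d_ph, tab$d_pco2)))
}
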