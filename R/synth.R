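# Seeded generators for cruise-like transects and seasonal forcing.
#
# These emulate the statistical structure the analysis assumes: meridional
# SST/SSS/TA gradients (strong along the Atlantic/Gulf-of-Maine margin,
# weak in the California Current System), labelled upwelling, river-plume
# and bloom perturbations, and sinusoidal seasonal drivers for a cold
# northern and a warm southern mixed-layer box. Gradient amplitudes are
# emulation choices, not data.

#' Default transect-generator configuration
#'
#' @param ta_slope,ta_intercept TA(S) relation, umol kg-1.
#' @param noise_ta,noise_dic 1-sigma measurement noise, umol kg-1
#'   (defaults 2, the nominal bottle-measurement uncertainty).
#' @param upwelling_dic,upwelling_sst,upwelling_no3,upwelling_do anomaly
#'   amplitudes applied at `upwelling` labels.
#' @param plume_sss,plume_dic anomalies at `river_plume` labels.
#' @param bloom_dic,bloom_do anomalies at `bloom` labels.
#' @return list of class `"transect_config"`.
#' @export
transect_config <- function(ta_slope = 50, ta_intercept = 530,
                            noise_ta = 2, noise_dic = 2,
                            upwelling_dic = 70, upwelling_sst = -4,
                            upwelling_no3 = 12, upwelling_do = -25,
                            plume_sss = -4, plume_dic = -20,
                            bloom_dic = -35, bloom_do = 18) {
  structure(as.list(environment()), class = "transect_config")
}

#' Generate a cruise-like bottle transect
#'
#' Builds an ordered south-to-north transect with margin-specific
#' hydrography. The Atlantic/Gulf-of-Maine margin spans 25-45 degrees N
#' with a strong SST decline (30 to 5 degrees C) and a salinity-driven TA
#' decline (~2355 to ~2080 umol kg-1); the California Current System spans
#' 32-48 degrees N with weak gradients. In `equilibrium` mode DIC is set
#' exactly to the DIC at equilibrium with `pco2_atm` given each sample's
#' TA, SST and SSS (all labels `background`); in `perturbed` mode labelled
#' upwelling (+DIC, +nitrate, -SST), river-plume (-SSS, -DIC) and bloom
#' (-DIC, +DO) anomalies plus measurement noise are superimposed.
#'
#' @param margin `"atlantic_gom"` or `"ccs"`.
#' @param n number of samples (>= 3).
#' @param mode `"equilibrium"` or `"perturbed"`.
#' @param seed integer seed; the output is a pure function of
#'   (arguments, seed).
#' @param pco2_atm atmospheric pCO2, uatm.
#' @param config a [transect_config()].
#' @param opts a [carb_options()] configuration.
#' @return data.frame of class `"transect"` in the bottle-CSV schema:
#'   `cruise, station, date_iso, lat_degn, lon_dege, sst_c, sss,
#'   ta_umol_kg, dic_umol_kg, do_percent, no3_umol_kg, po4_umol_kg,
#'   sio4_umol_kg, label`.
#' @export
make_transect <- function(margin = c("atlantic_gom", "ccs"), n = 60,
                          mode = c("equilibrium", "perturbed"), seed = 1,
                          pco2_atm = 395, config = transect_config(),
                          opts = carb_options()) {
  margin <- match.arg(margin)
  mode <- match.arg(mode)
  if (n < 3) stop("n must be at least 3")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  if (margin == "atlantic_gom") {
    lat <- seq(25, 45, length.out = n)
    lon <- -80 + 0.6 * (lat - 25)
    sst <- 30 - 1.25 * (lat - 25) + stats::rnorm(n, 0, 0.3)
    sss <- 36.5 - 0.275 * (lat - 25) + stats::rnorm(n, 0, 0.1)
    p_lab <- c(background = 0.70, upwelling = 0, river_plume = 0.15,
               bloom = 0.15)
  } else {
    lat <- seq(32, 48, length.out = n)
    lon <- -117 - 0.45 * (lat - 32)
    sst <- 16 - 0.15 * (lat - 32) + stats::rnorm(n, 0, 0.3)
    sss <- 33.6 - 0.04 * (lat - 32) + stats::rnorm(n, 0, 0.1)
    p_lab <- c(background = 0.60, upwelling = 0.25, river_plume = 0,
               bloom = 0.15)
  }
  label <- if (mode == "equilibrium") rep("background", n) else
    sample(names(p_lab), n, replace = TRUE, prob = p_lab)

  no3 <- pmax(stats::rnorm(n, 0.4, 0.1), 0)
  do_pct <- stats::rnorm(n, 100, 1.5)
  up <- label == "upwelling"; pl <- label == "river_plume"; bl <- label == "bloom"
  sst[up] <- sst[up] + config$upwelling_sst
  sss[pl] <- sss[pl] + config$plume_sss
  no3[up] <- no3[up] + config$upwelling_no3
  do_pct[up] <- do_pct[up] + config$upwelling_do
  do_pct[bl] <- do_pct[bl] + config$bloom_do
  do_pct[pl] <- do_pct[pl] + 5

  po4 <- pmax(stats::rnorm(n, 0.1, 0.03), 0)
  sio4 <- pmax(stats::rnorm(n, 2, 0.5), 0)
  ta <- config$ta_slope * sss + config$ta_intercept + stats::rnorm(n, 0, config$noise_ta)
  dic_eq <- carb_solve_pco2(pco2_atm, ta, sst, sss, po4, sio4, opts = opts)$dic
  if (mode == "equilibrium") {
    dic <- dic_eq
  } else {
    ddic <- numeric(n)
    ddic[up] <- config$upwelling_dic
    ddic[pl] <- config$plume_dic
    ddic[bl] <- config$bloom_dic
    dic <- dic_eq + ddic + stats::rnorm(n, 0, config$noise_dic)
  }

  structure(data.frame(
    cruise = paste0("SYN-", toupper(margin)),
    station = seq_len(n),
    date_iso = format(as.Date("2016-07-01") + seq_len(n) - 1, "%Y-%m-%d"),
    lat_degn = lat, lon_dege = lon, sst_c = sst, sss = sss,
    ta_umol_kg = ta, dic_umol_kg = dic, do_percent = do_pct,
    no3_umol_kg = no3,
    po4_umol_kg = po4,
    sio4_umol_kg = sio4,
    label = label, stringsAsFactors = FALSE),
    class = c("transect", "data.frame"))
}

#' Generate seasonal forcing for the box model
#'
#' Sinusoidal SST and SSS (cold-winter north-west Atlantic preset `"nwa"`:
#' SST 3-17 degrees C with a mid-February minimum and SSS highest in
#' winter with a summer minimum; warm South Atlantic Bight preset `"sab"`:
#' SST 20-28 degrees C), winds of 7 m s-1 in the summer half-year and
#' 10.5 m s-1 in winter with 15-day ramps at the transitions, a Gaussian
#' spring chlorophyll bloom sized so peak NCP is near 0.1 mmol C m-3
#' day-1, and (for `"nwa"`) 0.1 mmol m-3 day-1 of vertical DIC supply on
#' the 155 days spanning October-February.
#'
#' @param region `"nwa"` or `"sab"`.
#' @param year_days series length in days (>= 365); the seasonal cycle
#'   repeats with period 365.
#' @param seed integer seed (relevant when noise is enabled).
#' @param sst_noise_sd,sss_noise_sd,chl_noise_sd optional 1-sigma daily
#'   Gaussian noise (defaults 0: deterministic drivers).
#' @param c_to_chl carbon-to-chlorophyll mass ratio for the NCP
#'   conversion.
#' @return data.frame: `day, sst_c, sss, wind_ms, chl_mg_m3,
#'   ncp_mmol_m3_d, mix_mmol_m3_d`.
#' @export
make_forcing <- function(region = c("nwa", "sab"), year_days = 365,
                         seed = 1, sst_noise_sd = 0, sss_noise_sd = 0,
                         chl_noise_sd = 0, c_to_chl = 60) {
  region <- match.arg(region)
  if (year_days < 365) stop("year_days must be at least 365")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  day <- seq_len(year_days)
  doy <- ((day - 1) %% 365) + 1
  phase <- cos(2 * pi * (doy - 45) / 365)   # +1 mid-February, -1 mid-August
  if (region == "nwa") {
    sst <- 10 - 7 * phase
    sss <- 32.3 + 0.5 * phase               # winter high, summer minimum
    bloom_day <- 105; bloom_amp <- 0.45; bloom_sd <- 14
    mix <- ifelse(doy >= 274 | doy <= 63, 0.1, 0)  # Oct 1 - Mar 4: 155 days
  } else {
    sst <- 24 - 4 * phase
    sss <- 36.2 + 0.2 * phase
    bloom_day <- 30; bloom_amp <- 0.25; bloom_sd <- 20
    mix <- rep(0, year_days)
  }
  # winds: 7 m/s in the summer half (doy 100-281), 10.5 in winter,
  # 15-day linear ramps centred on the transitions
  ramp <- function(x) pmin(pmax(x, 0), 1)
  r_on <- ramp((doy - 92.5) / 15)
  r_off <- ramp((doy - 273.5) / 15)
  wind <- 10.5 - 3.5 * pmax(r_on - r_off, 0)

  chl <- 0.5 + bloom_amp * exp(-((doy - bloom_day)^2) / (2 * bloom_sd^2))
  if (sst_noise_sd > 0) sst <- sst + stats::rnorm(year_days, 0, sst_noise_sd)
  if (sss_noise_sd > 0) sss <- sss + stats::rnorm(year_days, 0, sss_noise_sd)
  if (chl_noise_sd > 0)
    chl <- pmax(chl + stats::rnorm(year_days, 0, chl_noise_sd), 0)

  data.frame(day = day, sst_c = sst, sss = sss, wind_ms = wind,
             chl_mg_m3 = chl, ncp_mmol_m3_d = chl_to_ncp(chl, c_to_chl),
             mix_mmol_m3_d = mix)
}

# save/restore the global RNG state so generators are pure in (args, seed)
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
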