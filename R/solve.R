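# Speciation solvers for the surface-seawater CO2 system, total pH scale.
# All user-facing concentrations in umol kg-1, pCO2 in uatm; internal
# arithmetic in mol kg-1 and atm.

# total alkalinity (mol kg-1) at a given total-scale [H+] with DIC fixed
.alk_at_h <- function(h, dic, k, pt, sit) {
  denom <- h^2 + k$K1 * h + k$K1 * k$K2
  hco3 <- dic * k$K1 * h / denom
  co3 <- dic * k$K1 * k$K2 / denom
  .alk_minor(h, k, pt, sit) + hco3 + 2 * co3
}

# non-carbonate alkalinity terms (borate, water, phosphate, silicate,
# minus free H+, bisulfate and HF), mol kg-1
.alk_minor <- function(h, k, pt, sit) {
  boh4 <- k$BT * k$KB / (k$KB + h)
  oh <- k$Kw / h
  hfree <- h / (1 + k$TS / k$KS)
  hso4 <- k$TS / (1 + k$KS / hfree)
  hf <- k$TF / (1 + k$KF / hfree)
  palk <- 0
  if (pt > 0) {
    pden <- h^3 + k$KP1 * h^2 + k$KP1 * k$KP2 * h + k$KP1 * k$KP2 * k$KP3
    palk <- pt * (k$KP1 * k$KP2 * h + 2 * k$KP1 * k$KP2 * k$KP3 - h^3) / pden
  }
  sialk <- if (sit > 0) sit * k$KSi / (k$KSi + h) else 0
  boh4 + oh + palk + sialk - hfree - hso4 - hf
}

.check_nutrients <- function(phosphate, silicate) {
  if (any(!is.finite(c(phosphate, silicate))) ||
      any(phosphate < 0) || any(silicate < 0))
    stop("nutrient concentrations must be non-negative and finite")
}

# assemble one solved row from [H+] (total, mol kg-1) and CO2 (mol kg-1)
.speciate <- function(h, co2, k) {
  hco3 <- k$K1 * co2 / h
  co3 <- k$K1 * k$K2 * co2 / h^2
  pco2 <- co2 / (k$K0 * k$fugfac) * 1e6
  list(ph = -log10(h), pco2 = pco2,
       co2 = co2 * 1e6, hco3 = hco3 * 1e6, co3 = co3 * 1e6,
       omega_arag = k$Ca * co3 / k$Ksp_arag)
}

.state_df <- function(temperature, salinity, ta, dic, sp,
                      phosphate, silicate) {
  structure(data.frame(temperature = temperature, salinity = salinity,
                       ta = ta, dic = dic, ph = sp$ph, pco2 = sp$pco2,
                       co2 = sp$co2, hco3 = sp$hco3, co3 = sp$co3,
                       omega_arag = sp$omega_arag, revelle = NA_real_,
                       phosphate = phosphate, silicate = silicate),
            class = c("carb_state", "data.frame"))
}

.root_ph <- function(f) {
  lo <- f(2); hi <- f(12)
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0)
    stop("no alkalinity-balance root in pH [2, 12]")
  stats::uniroot(f, c(2, 12), tol = 1e-9)$root
}

#' Solve the CO2 system from DIC and total alkalinity
#'
#' Finds the total-scale pH at which the alkalinity balance
#' \eqn{TA = [HCO_3^-] + 2[CO_3^{2-}] + [B(OH)_4^-] + [OH^-] - [H^+]_F
#' - [HSO_4^-] - [HF] + (phosphate, silicate terms)} closes for the given
#' DIC, then reports the full speciation: pCO2, the three carbonate
#' species, and the aragonite saturation state
#' \eqn{\Omega_{arag} = [Ca^{2+}][CO_3^{2-}]/K_{sp}}.
#'
#' All arguments are vectorised over samples.
#'
#' @param dic dissolved inorganic carbon, umol kg-1 (> 0).
#' @param ta total alkalinity, umol kg-1 (> 0); DIC/TA must lie in
#'   (0.4, 1.3).
#' @param temperature,salinity in-situ conditions (see [carb_constants()]).
#' @param phosphate,silicate nutrient totals, umol kg-1 (default 0).
#' @param opts a [carb_options()] configuration.
#' @return A data.frame of class `"carb_state"` with one row per sample and
#'   columns `temperature, salinity, ta, dic, ph, pco2, co2, hco3, co3,
#'   omega_arag, revelle, phosphate, silicate` (units as inputs; `revelle`
#'   is `NA` until filled by [revelle_factor()]).
#' @seealso [carb_solve_pco2()], [carb_solve_ph()]
#' @export
#' @examples
#' carb_solve(2038.6, 2280, temperature = 18, salinity = 35)
carb_solve <- function(dic, ta, temperature, salinity,
                       phosphate = 0, silicate = 0, opts = carb_options()) {
  n <- max(length(dic), length(ta), length(temperature), length(salinity),
           length(phosphate), length(silicate))
  dic <- rep_len(dic, n); ta <- rep_len(ta, n)
  temperature <- rep_len(temperature, n); salinity <- rep_len(salinity, n)
  phosphate <- rep_len(phosphate, n); silicate <- rep_len(silicate, n)
  .check_nutrients(phosphate, silicate)
  if (any(dic <= 0) || any(ta <= 0)) stop("DIC and TA must be positive")
  r <- dic / ta
  if (any(r <= 0.4 | r >= 1.3))
    stop("DIC/TA ratio outside (0.4, 1.3): ", signif(r[which.max(abs(r - 0.85))], 4))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    k <- carb_constants(temperature[i], salinity[i], opts)
    dic_m <- dic[i] * 1e-6; ta_m <- ta[i] * 1e-6
    pt <- phosphate[i] * 1e-6; sit <- silicate[i] * 1e-6
    ph <- .root_ph(function(p) .alk_at_h(10^(-p), dic_m, k, pt, sit) - ta_m)
    h <- 10^(-ph)
    denom <- h^2 + k$K1 * h + k$K1 * k$K2
    co2 <- dic_m * h^2 / denom
    out[[i]] <- .state_df(temperature[i], salinity[i], ta[i], dic[i],
                          .speciate(h, co2, k), phosphate[i], silicate[i])
  }
  do.call(rbind, out)
}

#' Solve the CO2 system from pCO2 and total alkalinity
#'
#' Dissolved CO2 follows Henry's law, \eqn{[CO_2] = K_0 f_{CO_2}} (with the
#' fugacity coefficient applied to pCO2 unless disabled in the options);
#' the alkalinity balance is then solved for pH and DIC is an output.
#'
#' @param pco2 seawater CO2 partial pressure, uatm (> 0); vectorised.
#' @inheritParams carb_solve
#' @return A `"carb_state"` data.frame (see [carb_solve()]).
#' @export
#' @examples
#' st <- carb_solve_pco2(395, 2280, temperature = 18, salinity = 35)
#' st$dic  # approx 2038.6
carb_solve_pco2 <- function(pco2, ta, temperature, salinity,
                            phosphate = 0, silicate = 0,
                            opts = carb_options()) {
  n <- max(length(pco2), length(ta), length(temperature), length(salinity),
           length(phosphate), length(silicate))
  pco2 <- rep_len(pco2, n); ta <- rep_len(ta, n)
  temperature <- rep_len(temperature, n); salinity <- rep_len(salinity, n)
  phosphate <- rep_len(phosphate, n); silicate <- rep_len(silicate, n)
  .check_nutrients(phosphate, silicate)
  if (any(pco2 <= 0) || any(ta <= 0)) stop("pCO2 and TA must be positive")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    k <- carb_constants(temperature[i], salinity[i], opts)
    ta_m <- ta[i] * 1e-6
    pt <- phosphate[i] * 1e-6; sit <- silicate[i] * 1e-6
    co2 <- k$K0 * k$fugfac * pco2[i] * 1e-6
    f <- function(p) {
      h <- 10^(-p)
      k$K1 * co2 / h + 2 * k$K1 * k$K2 * co2 / h^2 +
        .alk_minor(h, k, pt, sit) - ta_m
    }
    ph <- .root_ph(f)
    h <- 10^(-ph)
    dic <- (co2 + k$K1 * co2 / h + k$K1 * k$K2 * co2 / h^2) * 1e6
    sp <- .speciate(h, co2, k)
    sp$pco2 <- pco2[i]  # exact by construction
    out[[i]] <- .state_df(temperature[i], salinity[i], ta[i], dic, sp,
                          phosphate[i], silicate[i])
  }
  do.call(rbind, out)
}

#' Solve the CO2 system from pH and total alkalinity
#'
#' Direct (root-free) evaluation: at known \[H+\] the alkalinity balance is
#' linear in DIC.
#'
#' @param ph total-scale pH, in \[2, 12\]; vectorised.
#' @inheritParams carb_solve
#' @return A `"carb_state"` data.frame (see [carb_solve()]).
#' @export
carb_solve_ph <- function(ph, ta, temperature, salinity,
                          phosphate = 0, silicate = 0,
                          opts = carb_options()) {
  n <- max(length(ph), length(ta), length(temperature), length(salinity),
           length(phosphate), length(silicate))
  ph <- rep_len(ph, n); ta <- rep_len(ta, n)
  temperature <- rep_len(temperature, n); salinity <- rep_len(salinity, n)
  phosphate <- rep_len(phosphate, n); silicate <- rep_len(silicate, n)
  .check_nutrients(phosphate, silicate)
  if (any(ph < 2 | ph > 12)) stop("pH outside [2, 12]")
  if (any(ta <= 0)) stop("TA must be positive")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    k <- carb_constants(temperature[i], salinity[i], opts)
    h <- 10^(-ph[i])
    pt <- phosphate[i] * 1e-6; sit <- silicate[i] * 1e-6
    carb_alk <- ta[i] * 1e-6 - .alk_minor(h, k, pt, sit)
    # carb_alk = DIC * (K1 h + 2 K1 K2)/denom
    denom <- h^2 + k$K1 * h + k$K1 * k$K2
    dic_m <- carb_alk * denom / (k$K1 * h + 2 * k$K1 * k$K2)
    if (dic_m <= 0) stop("pH-TA pair implies non-positive DIC")
    co2 <- dic_m * h^2 / denom
    out[[i]] <- .state_df(temperature[i], salinity[i], ta[i], dic_m * 1e6,
                          .speciate(h, co2, k), phosphate[i], silicate[i])
  }
  do.call(rbind, out)
}

#' Alkalinity-balance residual of a solved state
#'
#' Diagnostic: recomputes \eqn{TA - (HCO_3^- + 2CO_3^{2-} + B(OH)_4^- +
#' OH^- + \ldots - H^+)} at the state's own pH; near zero for any state
#' returned by the solvers.
#'
#' @param state a `"carb_state"` row (or data.frame; vectorised).
#' @param opts the [carb_options()] the state was solved with.
#' @return residual in mol kg-1.
#' @export
alk_residual <- function(state, opts = carb_options()) {
  vapply(seq_len(nrow(state)), function(i) {
    k <- carb_constants(state$temperature[i], state$salinity[i], opts)
    h <- 10^(-state$ph[i])
    pt <- state$phosphate[i] * 1e-6; sit <- state$silicate[i] * 1e-6
    state$ta[i] * 1e-6 - .alk_at_h(h, state$dic[i] * 1e-6, k, pt, sit)
  }, numeric(1))
}
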