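# Open-system vs closed-system temperature sensitivity of the CO2 system.
#
# Closed system: a parcel isolated from the atmosphere (constant DIC and
# TA) re-equilibrates internally as temperature changes. Open system: the
# parcel stays in full gas equilibrium with a fixed atmospheric pCO2, so
# DIC adjusts through air-sea exchange. The gas-exchange decomposition
# attributes the difference between the two regimes to exchange.

.curve_row <- function(st, k) {
  data.frame(t_c = st$temperature, co2 = st$co2, pco2 = st$pco2,
             h = 10^(-st$ph) * 1e9, ph = st$ph, co3 = st$co3,
             omega_arag = st$omega_arag, dic = st$dic,
             k0 = k$K0, k1_over_k2 = k$K1 / k$K2)
}

.as_curve <- function(df, regime) {
  structure(df, class = c("temperature_curve", "data.frame"), regime = regime)
}

#' Closed-system temperature curve
#'
#' Re-solves a reference parcel at each grid temperature holding DIC and TA
#' fixed (no gas exchange). `h` is reported in nmol kg-1.
#'
#' @param ref a single solved `"carb_state"` row.
#' @param t_grid strictly increasing temperature grid, degrees C.
#' @param opts a [carb_options()] configuration.
#' @return A data.frame of class `"temperature_curve"` with columns
#'   `t_c, co2, pco2, h, ph, co3, omega_arag, dic, k0, k1_over_k2` and
#'   attribute `regime = "closed"`.
#' @export
closed_system_curve <- function(ref, t_grid = seq(0, 30, by = 0.5),
                                opts = carb_options()) {
  stopifnot(inherits(ref, "carb_state"), nrow(ref) == 1L)
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing")
  rows <- lapply(t_grid, function(tc) {
    st <- carb_solve(ref$dic, ref$ta, tc, ref$salinity,
                     ref$phosphate, ref$silicate, opts)
    .curve_row(st, carb_constants(tc, ref$salinity, opts))
  })
  .as_curve(do.call(rbind, rows), "closed")
}

#' Open-system temperature curve
#'
#' Solves the parcel at each grid temperature in full equilibrium with a
#' fixed atmospheric pCO2 (constant-pCO2 condition); DIC varies.
#'
#' @param ta total alkalinity, umol kg-1.
#' @param salinity practical salinity.
#' @param pco2_atm atmospheric pCO2, uatm.
#' @inheritParams closed_system_curve
#' @return A `"temperature_curve"` with attribute `regime = "open"`.
#' @export
open_system_curve <- function(ta, salinity, pco2_atm,
                              t_grid = seq(0, 30, by = 0.5),
                              opts = carb_options()) {
  stopifnot(ta > 0, pco2_atm > 0)
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing")
  rows <- lapply(t_grid, function(tc) {
    st <- carb_solve_pco2(pco2_atm, ta, tc, salinity, opts = opts)
    .curve_row(st, carb_constants(tc, salinity, opts))
  })
  .as_curve(do.call(rbind, rows), "open")
}

#' Gas-exchange decomposition of the open-system curve
#'
#' Per species, `term(T) = open(T) - closed(T) + open(ref_t)`: the part of
#' the open-system temperature response attributable to air-sea exchange,
#' anchored so the term equals the open-system value at the reference
#' temperature. The closed curve must be anchored at the open-curve state
#' at `ref_t` for the decomposition to be meaningful.
#'
#' @param open,closed `"temperature_curve"` objects on the same grid.
#' @param ref_t reference temperature, degrees C; must lie on the grid.
#' @return A `"temperature_curve"` with attribute `regime = "gas_exchange"`.
#' @export
gas_exchange_term <- function(open, closed, ref_t) {
  stopifnot(inherits(open, "temperature_curve"),
            inherits(closed, "temperature_curve"))
  if (!isTRUE(all.equal(open$t_c, closed$t_c)))
    stop("open and closed curves must share the same temperature grid")
  i_ref <- which(abs(open$t_c - ref_t) < 1e-9)
  if (length(i_ref) != 1L) stop("ref_t must be a grid point: ", ref_t)
  species <- setdiff(names(open), "t_c")
  out <- open
  for (sp in species)
    out[[sp]] <- open[[sp]] - closed[[sp]] + open[[sp]][i_ref]
  .as_curve(out, "gas_exchange")
}

#' Closed-system temperature normalization
#'
#' Re-solves a state at a target temperature with DIC and TA unchanged
#' (no gas exchange), the standard way to remove the thermodynamic
#' temperature signal from pCO2, pH and Omega when comparing samples
#' collected at different SST (typically `t_target = 25`).
#'
#' @param state a `"carb_state"` data.frame (vectorised over rows).
#' @param t_target target temperature, degrees C.
#' @param opts a [carb_options()] configuration.
#' @return A `"carb_state"` data.frame at `t_target`.
#' @export
normalize_to_temperature <- function(state, t_target = 25,
                                     opts = carb_options()) {
  stopifnot(inherits(state, "carb_state"))
  carb_solve(state$dic, state$ta, t_target, state$salinity,
             state$phosphate, state$silicate, opts)
}

#' Critical pH of maximum sensitivity to CO2 addition
#'
#' The pH at which \[CO2\] = \[CO3^2-\] (equivalently DIC is close to TA),
#' where the second term of
#' \eqn{pH = -0.5\log_{10}(K_1K_2) - 0.5\log_{10}([CO_2]/[CO_3^{2-}])}
#' vanishes; seawater near this point is least buffered against CO2
#' addition. Colder water has a higher critical pH.
#'
#' @param temperature,salinity conditions (vectorised over temperature).
#' @param opts a [carb_options()] configuration.
#' @return pH on the total scale, \eqn{-0.5\log_{10}(K_1K_2)}.
#' @export
#' @examples
#' critical_ph(c(3, 10, 30), 35)  # 7.71, 7.60, 7.35
critical_ph <- function(temperature, salinity = 35, opts = carb_options()) {
  vapply(temperature, function(tc) {
    k <- carb_constants(tc, salinity, opts)
    -0.5 * log10(k$K1 * k$K2)
  }, numeric(1))
}

#' Revelle factor by central finite difference
#'
#' \eqn{RF = (\Delta pCO_2/pCO_2) / (\Delta DIC / DIC)} at constant
#' temperature, salinity and TA, estimated by re-solving the state at
#' DIC +/- `delta_dic` and taking the symmetric difference.
#'
#' @param state a `"carb_state"` data.frame (vectorised over rows).
#' @param delta_dic half-width of the DIC perturbation, umol kg-1, in
#'   (0, 2\].
#' @param opts a [carb_options()] configuration.
#' @return numeric vector of Revelle factors (dimensionless).
#' @export
revelle_factor <- function(state, delta_dic = 1, opts = carb_options()) {
  stopifnot(inherits(state, "carb_state"),
            delta_dic > 0, delta_dic <= 2)
  vapply(seq_len(nrow(state)), function(i) {
    s <- state[i, ]
    up <- carb_solve(s$dic + delta_dic, s$ta, s$temperature, s$salinity,
                     s$phosphate, s$silicate, opts)
    dn <- carb_solve(s$dic - delta_dic, s$ta, s$temperature, s$salinity,
                     s$phosphate, s$silicate, opts)
    ((up$pco2 - dn$pco2) / s$pco2) / ((2 * delta_dic) / s$dic)
  }, numeric(1))
}

#' Tidy a temperature curve for export
#'
#' @param curve a `"temperature_curve"`.
#' @return long data.frame with columns `t_c, regime, species, value`.
#' @export
tidy_curve <- function(curve) {
  stopifnot(inherits(curve, "temperature_curve"))
  species <- setdiff(names(curve), "t_c")
  out <- do.call(rbind, lapply(species, function(sp)
    data.frame(t_c = curve$t_c, regime = attr(curve, "regime"),
               species = sp, value = curve[[sp]])))
  rownames(out) <- NULL
  out
}
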