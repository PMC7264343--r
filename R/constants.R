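#' Configuration of the carbonate-system constant set
#'
#' Collects the switchable choices behind [carb_constants()] and the
#' speciation solvers. Defaults mirror the conventional CO2SYS surface-water
#' setup: carbonic acid constants from the Mehrbach et al. (1973)
#' measurements as refitted by Dickson & Millero (1987), total borate from
#' Uppstrom (1974), boric acid from Dickson (1990), water from Millero
#' (1995), aragonite solubility from Mucci (1983), calcium proportional to
#' salinity after Riley & Tongudai (1967), and Henry's law applied to the
#' CO2 fugacity (Weiss 1974 virial correction) rather than to the raw
#' partial pressure.
#'
#' @param k1k2 carbonic-acid constant formulation: `"dm87"` (Dickson &
#'   Millero 1987 refit, seawater scale converted to total — the default)
#'   or `"lueker"` (Lueker et al. 2000 total-scale refit).
#' @param borate total-borate/salinity ratio: `"uppstrom"` (default) or
#'   `"lee"` (Lee et al. 2010).
#' @param fugacity logical; apply the Weiss (1974) fugacity correction when
#'   converting between pCO2 and dissolved CO2 (default `TRUE`).
#' @return A list of class `"carb_options"`.
#' @export
#' @examples
#' carb_options()
#' carb_options(k1k2 = "lueker", fugacity = FALSE)
carb_options <- function(k1k2 = c("dm87", "lueker"),
                         borate = c("uppstrom", "lee"),
                         fugacity = TRUE) {
  k1k2 <- match.arg(k1k2)
  borate <- match.arg(borate)
  stopifnot(is.logical(fugacity), length(fugacity) == 1L)
  structure(list(k1k2 = k1k2, borate = borate, fugacity = fugacity),
            class = "carb_options")
}

#' Seawater CO2-system equilibrium constants
#'
#' Evaluates the full constant set for the surface-seawater CO2 system on
#' the total proton scale at 0 dbar: the CO2 solubility `K0` (mol kg-1
#' atm-1, Weiss 1974), the carbonic acid dissociation constants `K1`, `K2`
#' (mol kg-1), boric acid `KB`, water `Kw`, bisulfate `KS`, hydrogen
#' fluoride `KF`, phosphoric acid `KP1`-`KP3`, silicic acid `KSi`, the
#' aragonite solubility product `Ksp_arag` (mol2 kg-2, Mucci 1983), and the
#' conservative totals: borate `BT`, sulfate `ST`, fluoride `FT` and
#' calcium `Ca` (mol kg-1), each proportional to salinity.
#'
#' Constants published on the seawater or free scale are converted to the
#' total scale with the sulfate and fluoride equilibria.
#'
#' @param temperature in-situ temperature, degrees C, in \[-2, 40\].
#' @param salinity practical salinity, in (0, 42\].
#' @param opts a [carb_options()] configuration.
#' @return A list of class `"carb_constants"`; also carries `fugfac`, the
#'   dimensionless fugacity coefficient at 1 atm (1 when
#'   `opts$fugacity = FALSE`).
#' @export
#' @examples
#' k <- carb_constants(18, 35)
#' k$K1 > k$K2
carb_constants <- function(temperature, salinity, opts = carb_options()) {
  stopifnot(length(temperature) == 1L, length(salinity) == 1L)
  if (!is.finite(temperature) || temperature < -2 || temperature > 40)
    stop("temperature out of range [-2, 40]: ", temperature)
  if (!is.finite(salinity) || salinity <= 0 || salinity > 42)
    stop("salinity out of range (0, 42]: ", salinity)

  TK <- temperature + 273.15
  lnTK <- log(TK)
  S <- salinity
  sqS <- sqrt(S)
  IonS <- 19.924 * S / (1000 - 1.005 * S)

  # conservative totals, mol kg-soln-1
  TS <- (0.14 / 96.062) * (S / 1.80655)
  TF <- (0.000067 / 18.998) * (S / 1.80655)
  BT <- switch(opts$borate,
               uppstrom = 0.0004157 * S / 35,
               lee      = 0.0004326 * S / 35)
  Ca <- 0.02128 / 40.087 * (S / 1.80655)

  # bisulfate (Dickson 1990a) and HF (Dickson & Riley 1979), free scale
  lnKS <- -4276.1 / TK + 141.328 - 23.093 * lnTK +
    (-13856 / TK + 324.57 - 47.986 * lnTK) * sqrt(IonS) +
    (35474 / TK - 771.54 + 114.723 * lnTK) * IonS -
    2698 / TK * IonS^1.5 + 1776 / TK * IonS^2
  KS <- exp(lnKS) * (1 - 0.001005 * S)
  KF <- exp(1590.2 / TK - 12.641 + 1.525 * sqrt(IonS)) * (1 - 0.001005 * S)
  sws_to_tot <- (1 + TS / KS) / (1 + TS / KS + TF / KF)
  free_to_tot <- 1 + TS / KS

  # CO2 solubility, Weiss (1974), mol kg-1 atm-1
  K0 <- exp(-60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
            S * (0.023517 - 0.023656 * (TK / 100) + 0.0047036 * (TK / 100)^2))

  if (opts$k1k2 == "dm87") {
    # Mehrbach refit by Dickson & Millero (1987), SWS scale
    pK1 <- 3670.7 / TK - 62.008 + 9.7944 * lnTK - 0.0118 * S + 0.000116 * S^2
    pK2 <- 1394.7 / TK + 4.777 - 0.0184 * S + 0.000118 * S^2
    K1 <- 10^(-pK1) * sws_to_tot
    K2 <- 10^(-pK2) * sws_to_tot
  } else {
    # Lueker et al. (2000), already total scale
    pK1 <- 3633.86 / TK - 61.2172 + 9.6777 * lnTK - 0.011555 * S + 0.0001152 * S^2
    pK2 <- 471.78 / TK + 25.929 - 3.16967 * lnTK - 0.01781 * S + 0.0001122 * S^2
    K1 <- 10^(-pK1)
    K2 <- 10^(-pK2)
  }

  # boric acid, Dickson (1990b), total scale
  lnKB <- (-8966.90 - 2890.53 * sqS - 77.942 * S + 1.728 * S^1.5 -
             0.0996 * S^2) / TK +
    148.0248 + 137.1942 * sqS + 1.62142 * S +
    (-24.4344 - 25.085 * sqS - 0.2474 * S) * lnTK + 0.053105 * sqS * TK
  KB <- exp(lnKB)

  # water, Millero (1995), SWS -> total
  lnKw <- 148.9802 - 13847.26 / TK - 23.6521 * lnTK +
    (118.67 / TK - 5.977 + 1.0495 * lnTK) * sqS - 0.01615 * S
  Kw <- exp(lnKw) * sws_to_tot

  # phosphoric and silicic acids, Yao & Millero / Millero (1995), SWS -> total
  lnKP1 <- -4576.752 / TK + 115.525 - 18.453 * lnTK +
    (-106.736 / TK + 0.69171) * sqS + (-0.65643 / TK - 0.01844) * S
  lnKP2 <- -8814.715 / TK + 172.0883 - 27.927 * lnTK +
    (-160.340 / TK + 1.3566) * sqS + (0.37335 / TK - 0.05778) * S
  lnKP3 <- -3070.75 / TK - 18.141 +
    (17.27039 / TK + 2.81197) * sqS + (-44.99486 / TK - 0.09984) * S
  lnKSi <- -8904.2 / TK + 117.385 - 19.334 * lnTK +
    (-458.79 / TK + 3.5913) * sqrt(IonS) + (188.74 / TK - 1.5998) * IonS +
    (-12.1652 / TK + 0.07871) * IonS^2
  KP1 <- exp(lnKP1) * sws_to_tot
  KP2 <- exp(lnKP2) * sws_to_tot
  KP3 <- exp(lnKP3) * sws_to_tot
  KSi <- exp(lnKSi) * (1 - 0.001005 * S) * sws_to_tot

  # aragonite solubility product, Mucci (1983)
  log10Ksp <- -171.945 - 0.077993 * TK + 2903.293 / TK + 71.595 * log10(TK) +
    (-0.068393 + 0.0017276 * TK + 88.135 / TK) * sqS -
    0.10018 * S + 0.0059415 * S^1.5
  Ksp_arag <- 10^log10Ksp

  # fugacity coefficient at 1 atm total pressure (Weiss 1974 virial form)
  fugfac <- 1
  if (isTRUE(opts$fugacity)) {
    RT <- 83.14472 * TK  # cm3 bar mol-1
    b <- -1636.75 + 12.0408 * TK - 0.0327957 * TK^2 + 3.16528e-5 * TK^3
    delta <- 57.7 - 0.118 * TK
    fugfac <- exp((b + 2 * delta) * 1.01325 / RT)
  }

  structure(list(T = temperature, S = salinity,
                 K0 = K0, K1 = K1, K2 = K2, KB = KB, Kw = Kw,
                 KS = KS, KF = KF, KP1 = KP1, KP2 = KP2, KP3 = KP3,
                 KSi = KSi, Ksp_arag = Ksp_arag,
                 BT = BT, TS = TS, TF = TF, Ca = Ca,
                 fugfac = fugfac, opts = opts),
            class = "carb_constants")
}
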