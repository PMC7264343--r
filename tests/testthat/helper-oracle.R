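# Independent reference implementation used as a cross-check oracle.
#
# Same published constant formulations as the package defaults, typed and
# organised separately, with a plain interval-bisection solver working on
# [H+] fractions rather than the package's Brent iteration on the
# alkalinity residual. No package internals are used.

oracle_constants <- function(tc, s) {
  tk <- tc + 273.15
  is_ <- 19.924 * s / (1000 - 1.005 * s)
  ts_ <- 0.14 / 96.062 * s / 1.80655
  tf_ <- 0.000067 / 18.998 * s / 1.80655
  ks <- exp(-4276.1 / tk + 141.328 - 23.093 * log(tk) +
              (-13856 / tk + 324.57 - 47.986 * log(tk)) * sqrt(is_) +
              (35474 / tk - 771.54 + 114.723 * log(tk)) * is_ -
              2698 / tk * is_^1.5 + 1776 / tk * is_^2) * (1 - 0.001005 * s)
  kf <- exp(1590.2 / tk - 12.641 + 1.525 * sqrt(is_)) * (1 - 0.001005 * s)
  sws2tot <- (1 + ts_ / ks) / (1 + ts_ / ks + tf_ / kf)
  k0 <- exp(9345.17 / tk - 60.2409 + 23.3585 * log(tk / 100) +
              s * (0.023517 - 0.00023656 * tk + 0.0047036 * (tk / 100)^2))
  k1 <- 10^(-(3670.7 / tk - 62.008 + 9.7944 * log(tk) -
                0.0118 * s + 0.000116 * s^2)) * sws2tot
  k2 <- 10^(-(1394.7 / tk + 4.777 - 0.0184 * s + 0.000118 * s^2)) * sws2tot
  kb <- exp((-8966.9 - 2890.53 * s^0.5 - 77.942 * s + 1.728 * s^1.5 -
               0.0996 * s^2) / tk + 148.0248 + 137.1942 * s^0.5 +
              1.62142 * s - (24.4344 + 25.085 * s^0.5 + 0.2474 * s) *
              log(tk) + 0.053105 * s^0.5 * tk)
  kw <- exp(148.9802 - 13847.26 / tk - 23.6521 * log(tk) +
              (118.67 / tk - 5.977 + 1.0495 * log(tk)) * s^0.5 -
              0.01615 * s) * sws2tot
  ksp <- 10^(-171.945 - 0.077993 * tk + 2903.293 / tk +
               71.595 * log10(tk) +
               (-0.068393 + 0.0017276 * tk + 88.135 / tk) * s^0.5 -
               0.10018 * s + 0.0059415 * s^1.5)
  list(k0 = k0, k1 = k1, k2 = k2, kb = kb, kw = kw, ks = ks, kf = kf,
       ksp = ksp, bt = 0.0004157 * s / 35, ts = ts_, tf = tf_,
       ca = 0.02128 / 40.087 * s / 1.80655,
       fug = exp(((-1636.75 + 12.0408 * tk - 0.0327957 * tk^2 +
                     3.16528e-5 * tk^3) + 2 * (57.7 - 0.118 * tk)) *
                   1.01325 / (83.14472 * tk)))
}

# total alkalinity (mol/kg) implied by H (total scale) and DIC, via
# ionisation fractions
oracle_alk <- function(h, dic, k) {
  d <- 1 + k$k1 / h + k$k1 * k$k2 / h^2
  a_hco3 <- (k$k1 / h) / d
  a_co3 <- (k$k1 * k$k2 / h^2) / d
  hfree <- h / (1 + k$ts / k$ks)
  dic * (a_hco3 + 2 * a_co3) +
    k$bt / (1 + h / k$kb) + k$kw / h -
    hfree - k$ts * hfree / (hfree + k$ks) - k$tf * hfree / (hfree + k$kf)
}

# bisection in pH, 80 halvings from [2, 12]
oracle_solve_dic_ta <- function(dic_u, ta_u, tc, s) {
  k <- oracle_constants(tc, s)
  dic <- dic_u * 1e-6
  ta <- ta_u * 1e-6
  lo <- 2; hi <- 12
  f <- function(p) oracle_alk(10^(-p), dic, k) - ta
  stopifnot(f(lo) < 0, f(hi) > 0)
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  ph <- (lo + hi) / 2
  h <- 10^(-ph)
  d <- 1 + k$k1 / h + k$k1 * k$k2 / h^2
  co2 <- dic / d
  co3 <- dic * (k$k1 * k$k2 / h^2) / d
  list(ph = ph, pco2 = co2 / (k$k0 * k$fug) * 1e6,
       omega = k$ca * co3 / k$ksp)
}
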