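# Independent full-chemistry oracle for the carbonate system.
#
# Same published equilibrium-constant fits as the package (Lueker et al.
# 2000, Dickson 1990, Millero 1995, Uppstrom 1974, Weiss 1974), entered
# separately, but a different solution route: the alkalinity balance is
# written in DIC speciation fractions and solved with stats::uniroot over
# pH, instead of the package's vectorized safeguarded Newton on [H+].
oracle_pco2 <- function(dic_umol, alk_umol, temp_c, sal) {
  tk <- temp_c + 273.15
  lntk <- log(tk)
  s <- sal
  k1 <- 10^-(3633.86 / tk - 61.2172 + 9.6777 * lntk -
               0.011555 * s + 0.0001152 * s^2)
  k2 <- 10^-(471.78 / tk + 25.929 - 3.16967 * lntk -
               0.01781 * s + 0.0001122 * s^2)
  kb <- exp((-8966.90 - 2890.53 * s^0.5 - 77.942 * s + 1.728 * s^1.5 -
               0.0996 * s^2) / tk +
              148.0248 + 137.1942 * s^0.5 + 1.62142 * s -
              (24.4344 + 25.085 * s^0.5 + 0.2474 * s) * lntk +
              0.053105 * s^0.5 * tk)
  kw <- exp(148.9652 - 13847.26 / tk - 23.6521 * lntk +
              (118.67 / tk - 5.977 + 1.0495 * lntk) * s^0.5 - 0.01615 * s)
  tk100 <- tk / 100
  k0 <- exp(-60.2409 + 93.4517 / tk100 + 23.3585 * log(tk100) +
              s * (0.023517 - 0.023656 * tk100 + 0.0047036 * tk100^2))
  bt <- 0.0004157 * s / 35
  dic <- dic_umol * 1e-6
  alk <- alk_umol * 1e-6
  # alkalinity balance in speciation fractions of DIC
  f <- function(ph) {
    h <- 10^-ph
    denom <- 1 + k1 / h + k1 * k2 / h^2
    a1 <- (k1 / h) / denom          # bicarbonate fraction
    a2 <- (k1 * k2 / h^2) / denom   # carbonate fraction
    dic * (a1 + 2 * a2) + bt / (1 + h / kb) + kw / h - h - alk
  }
  ph <- stats::uniroot(f, c(3, 12), tol = 1e-12)$root
  h <- 10^-ph
  co2 <- dic / (1 + k1 / h + k1 * k2 / h^2)
  co2 / k0 * 1e6
}

# Revelle factor of the full-chemistry oracle by central finite differences
oracle_revelle <- function(dic_umol, alk_umol, temp_c, sal, rel = 0.005) {
  d <- dic_umol * rel
  p1 <- oracle_pco2(dic_umol + d, alk_umol, temp_c, sal)
  p0 <- oracle_pco2(dic_umol - d, alk_umol, temp_c, sal)
  (log(p1) - log(p0)) / (log(dic_umol + d) - log(dic_umol - d))
}
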