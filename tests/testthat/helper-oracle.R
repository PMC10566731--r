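# Frozen reference values from an independent implementation of the
# published carbonate-constant formulations (Lueker K1/K2, Dickson KS/KB,
# Perez & Fraga KF, Weiss K0, Millero KW, Mucci KspAr), computed before the
# package was written. Used for cross-implementation equivalence checks.
oracle_grid <- data.frame(
  pH   = c(7.20, 7.20, 7.20, 7.60, 7.60, 7.60, 8.00, 8.00, 8.00, 8.30, 8.30, 8.30),
  TA   = c(1900.0, 2150.0, 2400.0, 1900.0, 2150.0, 2400.0, 1900.0, 2150.0, 2400.0, 1900.0, 2150.0, 2400.0),
  sal  = c(26.0, 31.0, 35.0, 26.0, 31.0, 35.0, 26.0, 31.0, 35.0, 26.0, 31.0, 35.0),
  temp = c(6.0, 14.0, 25.0, 6.0, 14.0, 25.0, 6.0, 14.0, 25.0, 6.0, 14.0, 25.0),
  DIC  = c(2023.221826, 2240.431257, 2445.833940, 1909.390259, 2119.631712, 2304.416867, 1812.747209, 1989.362602, 2117.947952, 1713.582293, 1846.303027, 1914.994780),
  pCO2 = c(2674.772243, 3097.027191, 3601.291973, 1039.223844, 1188.213623, 1351.815245, 390.230620, 433.583141, 470.463192, 178.871763, 191.003528, 194.987769),
  omega_ar = c(0.189216, 0.335121, 0.626674, 0.463853, 0.811243, 1.484227, 1.098986, 1.867794, 3.259183, 2.005454, 3.275654, 5.377624)
)

oracle_consts <- list(
  T25_S35 = list(K0 = 2.83918818e-02, K1 = 1.42182814e-06,
                 K2 = 1.08155475e-09, KB = 2.52657299e-09,
                 KW = 6.15550725e-14, KS = 1.00302071e-01,
                 KF = 2.26109792e-03, KspAr = 6.48175907e-07),
  T11_S30 = list(K0 = 4.36988330e-02, K1 = 9.94156410e-07,
                 K2 = 5.63712415e-10, KB = 1.60318789e-09,
                 KW = 1.49551569e-14, KS = 1.56278674e-01,
                 KF = 2.48821987e-03, KspAr = 5.70709987e-07)
)
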