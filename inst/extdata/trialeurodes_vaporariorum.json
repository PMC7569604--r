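{
  "species": "Trialeurodes vaporariorum",
  "host": "potato (cv. Canchan)",
  "provenance": "Constant-temperature life tables at 10, 15, 18, 20, 25, 28 and 32 C; fluctuating-temperature calibration at one Andean highland site.",
  "sex_ratio": 0.5,
  "development": {
    "egg":      { "D_min": 4.98, "T_opt": 27.4, "k": 0.15 },
    "nymph":    { "D_min": 9.94, "T_opt": 25.4, "k": 0.11 },
    "puparium": { "D_min": 3.46, "T_opt": 23.0, "k": 0.24 }
  },
  "mortality": {
    "egg":      { "H": 3.9e-06,  "B": 0.903, "T_opt": 21.8 },
    "nymph":    { "H": 6.32e-06, "B": 1.179, "T_opt": 21.8 },
    "puparium": { "H": 0.018,    "B": 2.389, "T_opt": 21.8 }
  },
  "adult_timing": {
    "intercept": 0.068,
    "slope": 0.0405,
    "factor_female": -0.0106,
    "factor_male": -0.3615
  },
  "fecundity": {
    "H": 8.885282,
    "Tl": 14.825526,
    "Bl": 1.583443,
    "Bh": 19.039554,
    "sigma_ln": 0.020216,
    "printed_params": {
      "comment": "Published constants retained as metadata only; they do not evaluate to plausible egg counts under the implemented family. The working parameters above are a least-squares refit to the observed mean fecundities (15-28 C).",
      "H": 34.9, "Tl": 12.9, "Bl": 1.86, "Bh": 39.5
    }
  },
  "links": {
    "egg":            { "family": "loglogistic", "delta": 0.044 },
    "nymph":          { "family": "loglogistic", "delta": 0.072 },
    "puparium":       { "family": "weibull",     "delta": 0.298 },
    "adult_survival": { "family": "lognormal",   "delta": 0.9271 },
    "oviposition":    { "family": "lognormal",   "delta": 0.7741 }
  },
  "adjustment_factors": {
    "mortality_B": 1.3,
    "adult_time": 2.0,
    "fecundity": 4.0
  }
}
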