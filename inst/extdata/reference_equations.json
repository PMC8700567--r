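{
  "version": "1.0",
  "source": "pediatric inspiratory chest CT reference cohort, n = 80, ages 6-17 years",
  "equations": [
    {"key": "tlc_ct_ml~age_years", "response": "tlc_ct_ml", "predictor": "age_years",
     "form": "linear", "a": -541.7, "b": 319.7, "r_squared": 0.59, "n": 80},
    {"key": "mean_hu~age_years", "response": "mean_hu", "predictor": "age_years",
     "form": "inverse", "a": -892.8, "b": 1160.4, "r_squared": 0.48, "n": 80},
    {"key": "lat_hu~age_years", "response": "lat_hu", "predictor": "age_years",
     "form": "inverse", "a": -1018.5, "b": 1034.1, "r_squared": 0.42, "n": 80},
    {"key": "hat_hu~age_years", "response": "hat_hu", "predictor": "age_years",
     "form": "inverse", "a": -767.2, "b": 1286.7, "r_squared": 0.50, "n": 80},
    {"key": "pct_high~age_years", "response": "pct_high", "predictor": "age_years",
     "form": "inverse", "a": 8.147, "b": 26.931, "r_squared": 0.49, "n": 80},
    {"key": "pct_low~tlc_ct_ml", "response": "pct_low", "predictor": "tlc_ct_ml",
     "form": "inverse", "a": -0.561, "b": 5876.6, "r_squared": 0.47, "n": 80},
    {"key": "pct_high~tlc_ct_ml", "response": "pct_high", "predictor": "tlc_ct_ml",
     "form": "inverse", "a": 8.771, "b": 4875.9, "r_squared": 0.76, "n": 80}
  ],
  "correlations": [
    {"x": "pct_low", "y": "age_years", "rho": -0.31, "n": 80},
    {"x": "pct_high", "y": "age_years", "rho": -0.67, "n": 80},
    {"x": "pct_low", "y": "tlc_ct_ml", "rho": -0.50, "n": 80},
    {"x": "pct_high", "y": "tlc_ct_ml", "rho": -0.79, "n": 80}
  ]
}
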