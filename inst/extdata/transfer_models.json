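{
  "model1": {
    "covariate": "gsl",
    "n_obs": 69,
    "error_df": 60,
    "rmse": 0.416,
    "adj_r2": 0.79,
    "rmsecv": 0.427,
    "terms": [
      {"term": "1",              "estimate": 4.16,      "se": 0.218,    "ci_low": 3.72,      "ci_high": 4.59,      "p": 0.001,  "p_censored": true},
      {"term": "iodineIn",       "estimate": 1.89,      "se": 0.343,    "ci_low": 1.21,      "ci_high": 2.58,      "p": 0.001,  "p_censored": true},
      {"term": "gsl",            "estimate": -0.152,    "se": 0.031,    "ci_low": -0.21,     "ci_high": -0.09,     "p": 0.001,  "p_censored": true},
      {"term": "iodineIn:gsl",   "estimate": 0.023,     "se": 0.011,    "ci_low": 0.00075,   "ci_high": 0.045,     "p": 0.043,  "p_censored": false},
      {"term": "iodineIn^2",     "estimate": -0.599,    "se": 0.16,     "ci_low": -0.91,     "ci_high": -0.28,     "p": 0.001,  "p_censored": true},
      {"term": "gsl^2",          "estimate": 0.0069,    "se": 0.0015,   "ci_low": 0.0038,    "ci_high": 0.0099,    "p": 0.001,  "p_censored": true},
      {"term": "iodineIn:gsl^2", "estimate": -0.0016,   "se": 0.00051,  "ci_low": -0.0026,   "ci_high": -0.00053,  "p": 0.0035, "p_censored": false},
      {"term": "iodineIn^3",     "estimate": 0.069,     "se": 0.02,     "ci_low": 0.029,     "ci_high": 0.11,      "p": 0.0012, "p_censored": false},
      {"term": "gsl^3",          "estimate": -4.31e-05, "se": 9.24e-06, "ci_low": -6.16e-05, "ci_high": -2.47e-05, "p": 0.001,  "p_censored": true}
    ]
  },
  "model2": {
    "covariate": "rapeseed",
    "n_obs": 69,
    "error_df": 63,
    "rmse": 0.382,
    "adj_r2": 0.83,
    "rmsecv": 0.393,
    "terms": [
      {"term": "1",          "estimate": 4.22,     "se": 0.184,    "ci_low": 3.85,     "ci_high": 4.59,     "p": 0.001, "p_censored": true},
      {"term": "iodineIn",   "estimate": 1.84,     "se": 0.303,    "ci_low": 1.24,     "ci_high": 2.45,     "p": 0.001, "p_censored": true},
      {"term": "rapeseed",   "estimate": -0.01,    "se": 0.002,    "ci_low": -0.015,   "ci_high": -0.0057,  "p": 0.001, "p_censored": true},
      {"term": "iodineIn^2", "estimate": -0.57,    "se": 0.141,    "ci_low": -0.85,    "ci_high": -0.29,    "p": 0.001, "p_censored": true},
      {"term": "rapeseed^2", "estimate": 2.87e-05, "se": 1.28e-05, "ci_low": 3.09e-06, "ci_high": 5.43e-05, "p": 0.029, "p_censored": false},
      {"term": "iodineIn^3", "estimate": 0.07,     "se": 0.018,    "ci_low": 0.03,     "ci_high": 0.10,     "p": 0.001, "p_censored": true}
    ]
  }
}
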