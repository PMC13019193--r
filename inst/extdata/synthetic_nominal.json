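{
  "_comment": "SYNTHETIC nominal parameter set (not the fitted murine values, which are not redistributable). Chosen once to give an acute-healing baseline: a 20 a.u. pathogen load into a resting system is cleared by day 8 with an early neutrophil burst, a delayed monocyte/M1 wave, late M2 accumulation and IL-6 excursions of order 1 a.u. See the methods vignette.",
  "alpha1": 30.0,
  "alpha2": -0.15,
  "beta": 0.5,
  "gamma1": 0.05,
  "gamma2": 1.0,
  "gamma3": 0.1,
  "gamma4": 0.1,
  "gamma5": 0.3,
  "delta1": 2.0,
  "delta2": 0.5,
  "delta3": 0.2,
  "mu1": 1.0,
  "mu2": 0.3,
  "mu3": 0.5,
  "mu4": 0.5,
  "Kn": 10.0,
  "n_hill": 2.0,
  "Cmax": 60.0,
  "theta_eff": 5.0,
  "kappa": 1.0
}
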