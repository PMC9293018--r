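{
  "_comment": "SYNTHETIC reference parameterization: chosen to reproduce the qualitative co-culture shape (diatom near-linear rise to ~1e7 cells/ml over 28 days, ~14-day bacterial lag). NOT fitted values from any experiment.",
  "nu_mu_D": 0.25,
  "nu_delta_D": 0.05,
  "nu_mu_B": 2.5,
  "nu_delta_B": 0.2,
  "lam": 0.05,
  "CC_D": 2e7,
  "CC_B": 1e9,
  "K_DOME": 1.5e6,
  "K_DOMB": 1.5e6,
  "delta_DOME": 0.01,
  "delta_DOMB": 0.01,
  "yield": 1,
  "B": 1e5,
  "D": 2e5,
  "DOM_E": 0,
  "DOM_B": 0
}
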