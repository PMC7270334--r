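{
  "_comment": "Default covariate coefficients for the one-compartment oral imatinib population PK model. Values are population estimates in the style of the published imatinib covariate model (typical clearance ~14.3 L/h, volume of distribution ~347 L, first-order absorption 0.61 1/h, oral bioavailability ~0.98), with additive sex effects and relative body-weight/age deviations. They are defaults, not a clinical reference: override with a study-specific constants file of the same schema.",
  "version": "1.0",
  "theta_a": 14.3,
  "theta_b": 347.0,
  "theta_1": 5.4,
  "theta_2": 0.8,
  "theta_3": -1.3,
  "theta_4": 62.0,
  "bw_mean": 70.0,
  "age_mean": 50.0,
  "ka": 0.61,
  "f": 0.98
}
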