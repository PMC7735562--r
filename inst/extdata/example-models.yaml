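# Dose-response models for the `simulate` CLI subcommand: one entry
# per treatment appearing in the layout CSV.  Fields mirror
# dose_response_model(); omitted fields use that constructor's
# defaults.
vehicle:
  theta_min: 0.15
  theta_max: 0.15
  expr_gain: 0
blank:
  theta_min: 0.15
  theta_max: 0.15
  expr_gain: 0
mo56HC:
  theta_min: 0.15
  theta_max: 0.85
  ec50_uM: 1
  hill: 1
  tox_dose_uM: 20
  expr_gain: 2.5
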