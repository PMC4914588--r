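# Example pipeline configuration. Every key is optional; anything omitted is
# filled from default_config(). Unknown keys are rejected. Units are encoded
# in the key suffixes (_m metres, _s seconds, _pa pascals, _pas Pa.s,
# _ms m/s). See ?default_config for the complete key set.
synth:
  radius_m: 0.01
  length_m: 0.09
  n_circ: 24
  n_axial: 30
  period_s: 1.0
  n_time: 64
  noise_sd: 0.0
  seed: 1
indices:
  ssi: holmes            # holmes | tawss: stimulus driving the cascade
rheology:
  mode: carreau_yasuda   # carreau_yasuda | plasma
permeability:
  pressure_mode: local_time_avg   # local_time_avg | uniform
  lp_threshold: 1.2e-11           # m^2.s/kg, atheroprone cutoff
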