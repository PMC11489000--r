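# Demo synthetic-cohort configuration: a small, fast run.
# Any key omitted here keeps its package default (see default_cohort_config()).
n_control: 2
n_vaper: 3
effects:
  hr_post_delta: 3.2
  bmi_q_slope: -0.037
imaging:
  shape: 48
  snr_sv: 40
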