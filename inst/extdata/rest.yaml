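# Reference rest configuration: every omitted key keeps its default.
ventilation:
  amplitude_m_per_s: 1
  period_s: 5
scenario:
  type: oedema
  tau_multipliers: [1, 2, 4, 8, 16, 32, 64, 128, 256, 512]
output_dir: ventopt-output
seed: 1
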