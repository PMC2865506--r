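# Example pitchsense configuration. Any subset of default_config() keys may
# be overridden; unit suffixes (_m, _N, _W, _m_s) are part of the key names.
energetics:
  prey_density_per_m3: 2500   # halving the density doubles energy per prey
pitch:
  max_deg: 70
seed: 42
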