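well:
  EwL: 0.45
  EwR: 0.45
  Em: 0.85
  w: 1.1
  e: 0.3
  m_gap: 0.6
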