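reaction_type: aldol
temperature: 298.15
points:
- name: INT1a
  role: intermediate
  cycle: A
  g_rel: 0.0
- name: RCa
  role: reactive_complex
  cycle: A
  g_rel: 1.0
- name: TS1a_RS
  role: transition_state
  cycle: A
  g_rel: 19.0
  product_config: RS
  face_pair: Si,Si
- name: TS1a_RR
  role: transition_state
  cycle: A
  g_rel: 20.447
  product_config: RR
  face_pair: Re,Si
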