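reaction_type: aldol
temperature: 298.15
points:
- name: INT1a_distal
  role: intermediate
  cycle: A
  g_rel: 0.0
  conformer: distal
- name: INT1a_proximal
  role: intermediate
  cycle: A
  g_rel: 0.3
  conformer: proximal
- name: INT1b_distal
  role: intermediate
  cycle: B
  g_rel: -0.5
  conformer: distal
- name: INT1b_proximal
  role: intermediate
  cycle: B
  g_rel: 0.2
  conformer: proximal
- name: RCa_proximal
  role: reactive_complex
  cycle: A
  g_rel: 1.0
  conformer: proximal
- name: RCb_distal
  role: reactive_complex
  cycle: B
  g_rel: 1.5
  conformer: distal
- name: TS1a_RS_proximal
  role: transition_state
  cycle: A
  g_rel: 18.0
  conformer: proximal
  product_config: RS
  face_pair: Si,Si
- name: TS1a_SR_proximal
  role: transition_state
  cycle: A
  g_rel: 19.4885031
  conformer: proximal
  product_config: SR
  face_pair: Re,Re
- name: TS1a_RR_proximal
  role: transition_state
  cycle: A
  g_rel: 19.5713099
  conformer: proximal
  product_config: RR
  face_pair: Re,Si
- name: TS1a_SS_proximal
  role: transition_state
  cycle: A
  g_rel: 20.2222211
  conformer: proximal
  product_config: SS
  face_pair: Si,Re
- name: TS1b_RS_distal
  role: transition_state
  cycle: B
  g_rel: 18.1912384
  conformer: distal
  product_config: RS
  face_pair: Si,Si
- name: TS1b_SR_distal
  role: transition_state
  cycle: B
  g_rel: 19.6797414
  conformer: distal
  product_config: SR
  face_pair: Re,Re
- name: TS1b_RR_distal
  role: transition_state
  cycle: B
  g_rel: 19.7625483
  conformer: distal
  product_config: RR
  face_pair: Re,Si
- name: TS1b_SS_distal
  role: transition_state
  cycle: B
  g_rel: 20.4134594
  conformer: distal
  product_config: SS
  face_pair: Si,Re
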