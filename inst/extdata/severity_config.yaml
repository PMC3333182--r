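proximity_A: 8.0
direct_interaction_A: 4.5
salt_bridge_A: 4.0
hbond_A: 3.5
last_domain_boundary: 720
gap_threshold_nt: 150
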