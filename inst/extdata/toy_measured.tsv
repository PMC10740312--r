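measured_id	value
glc_to_X_via_A	5.3
glc_to_X_total	5.6
biomass	5.6
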