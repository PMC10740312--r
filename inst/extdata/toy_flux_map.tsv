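measured_id	mode	steps
glc_to_X_via_A	chain	P_A1;P_A2
glc_to_X_total	parallel	P_A1;P_B1
biomass	chain	BIOMASS
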