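profile	sex	body_weight_kg	cardiac_output_L_h	liver_mass_g	mppgl_mg_per_g	hematocrit
adult_male	male	70	390	1493	32	0.45
adult_female	female	60	354	1350	32	0.40
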