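profile	organ	volume_L	flow_L_h
adult_male	lung	0.5	390
adult_male	arterial	1.7	NA
adult_male	venous	3.9	NA
adult_male	liver	1.493	25.4
adult_male	gut	1.2	58.5
adult_male	brain	1.45	46.8
adult_male	kidney	0.31	74.1
adult_male	adipose	14.5	19.5
adult_male	muscle	29	66.3
adult_male	skin	3.3	19.5
adult_male	rest	5	79.9
adult_female	lung	0.45	354
adult_female	arterial	1.4	NA
adult_female	venous	3.3	NA
adult_female	liver	1.35	23.0
adult_female	gut	1.1	53.1
adult_female	brain	1.3	42.5
adult_female	kidney	0.28	60.2
adult_female	adipose	17	30.1
adult_female	muscle	20	42.5
adult_female	skin	2.7	17.7
adult_female	rest	4	84.9
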