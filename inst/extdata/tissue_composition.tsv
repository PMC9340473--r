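tissue	f_water	f_neutral_lipid	f_phospholipid	f_protein	intracellular_ph
adipose	0.15	0.80	0.002	0.05	7.0
brain	0.77	0.051	0.0565	0.08	7.0
gut	0.76	0.0487	0.0163	0.14	7.0
kidney	0.78	0.0207	0.0162	0.17	7.0
liver	0.745	0.0348	0.0252	0.20	7.0
lung	0.78	0.003	0.009	0.13	7.0
muscle	0.76	0.0238	0.0072	0.18	7.0
skin	0.72	0.0284	0.0111	0.23	7.0
rest	0.76	0.04	0.01	0.15	7.0
fetus	0.88	0.005	0.005	0.09	7.0
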