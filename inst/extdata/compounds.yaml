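# Reference parameterizations for the three case-study compounds.
# Keys carry explicit unit suffixes. fu_plasma is the unbound fraction.
ibuprofen:
  mw_g_per_mol: 206.29
  log_p: 2.23
  ionization: acid
  pka: 4.5
  solubility_mg_per_ml: 0.0684
  fu_plasma: 0.01
  ka_per_h: 2.1
  fa: 1.0
amiodarone:
  mw_g_per_mol: 645.31
  log_p: 7.57
  ionization: base
  pka: 9.08
  solubility_mg_per_ml: 0.00476
  fu_plasma: 0.06
  ka_per_h: 0.323
  fa: 0.3
  oral_bioavailability_f: 0.65
chlorpyrifos:
  mw_g_per_mol: 350.57
  log_p: 4.96
  ionization: neutral
  solubility_mg_per_ml: 0.0014
  fu_plasma: 0.03
  fa: 0.32
  peff_cm_per_s: 6.16e-5
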