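# RPMI-1640-like medium for Recon-style human models, keyed by conventional
# exchange reaction ids (mmol/gDW/h uptake magnitudes). Composition is
# config data: adjust ids to the loaded reconstruction.
uptakes:
  EX_glc(e): 5.0
  EX_o2(e): 20.0
  EX_arg_L(e): 0.5
  EX_asn_L(e): 0.25
  EX_asp_L(e): 0.15
  EX_cys_L(e): 0.3
  EX_gln_L(e): 2.0
  EX_glu_L(e): 0.15
  EX_gly(e): 0.15
  EX_his_L(e): 0.1
  EX_ile_L(e): 0.4
  EX_leu_L(e): 0.4
  EX_lys_L(e): 0.3
  EX_met_L(e): 0.1
  EX_phe_L(e): 0.1
  EX_pro_L(e): 0.2
  EX_ser_L(e): 0.3
  EX_thr_L(e): 0.2
  EX_trp_L(e): 0.03
  EX_tyr_L(e): 0.1
  EX_val_L(e): 0.2
  EX_ca2(e): 0.5
  EX_cl(e): 1.0
  EX_k(e): 1.0
  EX_na1(e): 1.0
  EX_pi(e): 1.0
  EX_so4(e): 0.5
  EX_fol(e): 0.01
  EX_ncam(e): 0.01
  EX_pydxn(e): 0.01
  EX_ribflv(e): 0.005
  EX_thm(e): 0.01
  EX_btn(e): 0.005
  EX_chol(e): 0.02
  EX_inost(e): 0.05
forced:
  EX_co2(e): 0.1
  biomass_reaction: 0.001
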