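# Default synthetic cohort configuration.
#
# SYNTHETIC STUDY CONDITIONS — NOT PATIENT-DERIVED. These class-conditional
# diameter distributions are stylised values chosen to reproduce the
# qualitative class structure of infant thoracic aortas (coarctation: D0
# markedly smaller and tighter, D3 and D1 smaller, DBCA larger and more
# variable, D5 larger); no individual patient data stand behind them.
n_per_class: 30
seed: 1
hemo_model: balance
v_inlet_mean: 0.75
v_inlet_sd: 0.30
p_base: 12.8
friction: 0.06
loss_coeff: 0.15
backup_frac: 0.6
redistribution: 0.2
noise_sd_v: 0.25
noise_sd_p: 0.8
flow_split:
  BCA: 0.16
  LCCA: 0.07
  LSCA: 0.08
  O5: 0.69
diameter_params:
  normal:
    mean: {D1: 10.4, D2: 9.6, D3: 8.6, D0: 7.7, D4: 9.0, D5: 6.9,
           DBCA: 4.6, DLCCA: 3.3, DLSCA: 3.6}
    sd:   {D1: 1.15, D2: 1.05, D3: 0.95, D0: 0.85, D4: 1.05, D5: 0.85,
           DBCA: 0.55, DLCCA: 0.45, DLSCA: 0.50}
  coa:
    mean: {D1: 9.2, D2: 9.4, D3: 6.8, D0: 2.9, D4: 9.3, D5: 7.6,
           DBCA: 5.6, DLCCA: 3.4, DLSCA: 3.7}
    sd:   {D1: 1.10, D2: 1.05, D3: 0.95, D0: 0.50, D4: 1.15, D5: 0.90,
           DBCA: 0.95, DLCCA: 0.50, DLSCA: 0.55}
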