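system,exp_dE_mV,exp_err_mV,mdcb_dE_mV,mdcb_err_mV,pbmc_dE_mV
m4D2,0,0,0,0,0
T19D,-28,1,-4,2,-35
M23N,1,1,14,2,0
R34Q,-31,1,-12,2,-11
R92Q,-32,1,-14,2,-14
DM,-56,1,-12,2,-67
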