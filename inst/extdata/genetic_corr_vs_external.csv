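indicator,UH,HH,KET,LON,FER,BCS
mean_complete,0.015,0.16,0.20,0.15,0.062,0.17
mean_early,0.025,0.17,0.18,0.22,0.067,0.20
mean_later,0.033,0.16,0.17,0.13,0.065,0.17
mean_prepartum,0.11,0.021,0.036,0.061,0.061,0.029
mean_neg_residuals,-0.047,0.021,-0.23,-0.13,0.051,-0.034
ln_var,0.11,0.16,0.24,0.12,0.056,0.12
r_auto,-0.16,-0.33,0.0019,0.0022,-0.44,-0.34
n_drops_per_100d,-0.063,-0.56,-0.24,0.16,-0.44,-0.56
mean_neg_residuals_in_drops,-0.031,-0.044,-0.11,-0.14,0.053,0.057
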