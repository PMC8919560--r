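indicator,r_xz
mean_neg_residuals,-0.93
ln_var,0.86
mean_neg_residuals_in_drops,-0.95
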