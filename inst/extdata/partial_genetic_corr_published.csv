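indicator,UH,HH,KET,LON,FER,BCS
mean_neg_residuals,-0.090,0.47,-0.12,0.026,0.30,0.34
ln_var,0.19,0.04,0.14,-0.018,0.0053,-0.052
mean_neg_residuals_in_drops,-0.054,0.35,0.26,0.0081,0.36,0.71
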