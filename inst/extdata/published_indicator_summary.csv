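indicator,mean,sd,min,max
mean_complete,10.90,769.63,-2912.94,3518.49
mean_early,405.50,1142.96,-3913.73,5803.58
mean_later,-55.89,741.57,-3133.34,3143.33
mean_prepartum,-97.99,1143.46,-4650.73,4859.06
mean_neg_residuals,-620.29,281.01,-1876.08,-157.27
ln_var,13.18,0.87,10.34,16.28
r_auto,0.32,0.19,-0.43,0.89
n_drops_per_100d,1.39,0.70,0.00,4.11
mean_neg_residuals_in_drops,-685.34,429.89,-2528.28,0.00
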