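quantity,value
density_june_mg_m3,4.73
density_july_mg_m3,1.13
planktonic_june_pct,90.6
planktonic_july_pct,80.3
planktonic_august_pct,75.5
planktonic_september_pct,76.6
planktonic_september_pelagic_median_pct,90
adj_mass_littoral_g,0.304
adj_mass_pelagic_g,0.275
larval_peak_littoral_pelagic_ratio,7
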