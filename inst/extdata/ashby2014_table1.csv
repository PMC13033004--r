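habitat,month,stage,n,mean_sl_mm,sem_sl_mm,mean_mass_g,sem_mass_g
littoral,June,larval,3,4.73,0.266,,
littoral,July,larval,3,4.62,0.246,,
littoral,August,juvenile,34,18.87,0.487,0.111,0.008
littoral,September,juvenile,46,23.86,0.254,0.241,0.008
shoreline,June,larval,2,4.15,0.065,,
shoreline,July,larval,4,4.75,0.269,,
shoreline,August,juvenile,32,18.03,0.504,0.106,0.011
shoreline,September,juvenile,29,23.99,0.376,0.229,0.012
pelagic,June,larval,2,4.48,0.63,,
pelagic,July,larval,4,5.32,0.249,,
pelagic,August,juvenile,32,22.23,0.376,0.218,0.011
pelagic,September,juvenile,58,27.48,0.355,0.325,0.012
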