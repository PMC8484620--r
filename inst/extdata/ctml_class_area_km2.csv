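class,year,area_km2
patch,1930,0.16
patch,1975,157.11
patch,2000,165.69
patch,2020,210.85
edge,1930,1086.55
edge,1975,2825.61
edge,2000,2910.84
edge,2020,3279.62
perforated,1930,0.67
perforated,1975,1876.53
perforated,2000,1430.23
perforated,2020,1693.21
core1,1930,42.18
core1,1975,422.32
core1,2000,474.32
core1,2020,509.25
core2,1930,49.34
core2,1975,157.51
core2,2000,182.84
core2,2020,207.65
core3,1930,23136.67
core3,1975,15881.84
core3,2000,14889.40
core3,2020,13168.56
total,1930,24315.56
total,1975,21320.92
total,2000,20053.32
total,2020,19069.14
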