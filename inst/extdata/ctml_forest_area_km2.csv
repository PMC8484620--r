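region,year,area_km2
eastern,1930,4607.92
eastern,1975,4084.94
eastern,2000,3781.68
eastern,2020,3548.48
central,1930,4336.84
central,1975,4162.02
central,2000,3917.77
central,2020,3771.95
western,1930,6703.66
western,1975,5590.97
western,2000,5186.52
western,2020,4993.85
far_western,1930,8667.14
far_western,1975,7482.98
far_western,2000,7167.34
far_western,2020,6754.86
total,1930,24315.56
total,1975,21320.92
total,2000,20053.32
total,2020,19069.14
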