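block,class,area_1930_km2,area_2020_km2,pct_change_published_abs
block1,patch,0.01,93.36,933500.00
block1,edge,297.17,950.68,219.91
block1,perforated,0.11,423.75,385127.27
block1,core1,15.89,177.85,1019.26
block1,core2,15.20,77.38,409.08
block1,core3,4279.55,1825.46,57.34
block1,total,4607.92,3548.48,22.99
block2,patch,0.14,75.10,53542.86
block2,edge,322.23,1252.36,288.65
block2,perforated,0.11,706.05,641763.64
block2,core1,4.28,186.38,4254.67
block2,core2,8.83,66.08,648.36
block2,core3,8331.55,4468.89,46.36
block2,total,8667.14,6754.86,22.06
block3,edge,219.92,544.19,147.45
block3,perforated,0.24,271.11,112862.50
block3,core1,13.20,77.71,488.71
block3,core2,9.99,26.24,162.66
block3,core3,4093.49,2829.29,30.88
block3,total,4336.84,3771.95,13.03
block4,edge,247.23,532.38,115.34
block4,perforated,0.21,292.29,139085.71
block4,core1,8.82,67.31,663.15
block4,core2,15.31,37.96,147.94
block4,core3,6432.07,4044.91,37.11
block4,total,6703.66,4993.85,25.51
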