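class,period,change_km2_published,pct_change_published
patch,1930_1975,156.95,NA
patch,1975_2000,8.58,5.46
patch,2000_2020,45.16,27.26
patch,1930_2020,210.70,NA
patch,1975_2020,NA,34.21
edge,1930_1975,1739.06,160.05
edge,1975_2000,85.23,3.02
edge,2000_2020,368.78,12.67
edge,1930_2020,2193.07,201.84
edge,1975_2020,NA,16.07
perforated,1930_1975,1875.86,NA
perforated,1975_2000,-446.30,-23.78
perforated,2000_2020,262.97,18.39
perforated,1930_2020,1692.54,NA
perforated,1975_2020,NA,-9.77
core1,1930_1975,380.14,901.23
core1,1975_2000,52.00,12.31
core1,2000_2020,34.93,7.36
core1,1930_2020,467.07,1107.33
core1,1975_2020,NA,20.58
core2,1930_1975,108.17,219.23
core2,1975_2000,25.34,16.08
core2,2000_2020,24.81,13.57
core2,1930_2020,158.31,320.86
core2,1975_2020,NA,31.83
core3,1930_1975,-7254.83,-31.36
core3,1975_2000,-992.44,-6.25
core3,2000_2020,-1720.84,-11.56
core3,1930_2020,-9968.11,-43.08
core3,1975_2020,NA,-17.08
total,1930_1975,-2994.64,-12.32
total,1975_2000,-1267.60,-5.95
total,2000_2020,-984.19,-4.91
total,1930_2020,-5246.42,-21.58
total,1975_2020,NA,-10.56
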