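region,period,pct_change_published_abs,annual_rate_published,pct_basis
eastern,1930_1975,11.35,-0.27,initial
eastern,1975_2000,7.42,-0.31,initial
eastern,2000_2020,6.57,-0.32,final
eastern,1930_2020,22.99,-0.29,initial
central,1930_1975,4.03,-0.09,initial
central,1975_2000,5.87,-0.24,initial
central,2000_2020,3.87,-0.19,final
central,1930_2020,13.03,-0.16,initial
western,1930_1975,16.60,-0.40,initial
western,1975_2000,7.23,-0.30,initial
western,2000_2020,3.86,-0.19,final
western,1930_2020,25.51,-0.33,initial
far_western,1930_1975,13.66,-0.33,initial
far_western,1975_2000,4.22,-0.17,initial
far_western,2000_2020,6.11,-0.30,final
far_western,1930_2020,22.06,-0.28,initial
total,1930_1975,12.32,-0.29,initial
total,1975_2000,5.95,-0.25,initial
total,2000_2020,5.16,-0.25,final
total,1930_2020,21.58,-0.27,initial
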