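region,participating,active,printed_pct
East Midlands,12,13,92
East of England,26,30,87
London,59,61,97
North East,12,13,92
North West,52,54,96
South Central,47,47,100
South East Coast,41,43,95
South West,45,46,98
Wales,36,39,92
West Midlands,40,40,100
Yorkshire & Humber,7,9,78
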