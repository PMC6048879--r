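region,total,at_linkage,partial,complete,printed_at_linkage_pct,printed_partial_pct,printed_complete_pct
East Midlands,102970,96498,96448,96448,93.7,99.9,99.9
East of England,262070,219216,219038,219038,83.6,99.9,99.9
London,443050,436073,388973,388970,98.4,89.2,89.2
North East,105225,99672,87656,87656,94.7,87.9,87.9
North West,375752,361339,335503,333132,96.2,92.8,92.2
South Central,469322,469322,467804,466069,100.0,99.7,99.3
South East Coast,388040,369537,362703,362676,95.2,98.2,98.1
South West,357656,353201,337712,337711,98.8,95.6,95.6
Wales,267513,242972,240679,225442,90.8,99.1,92.8
West Midlands,333920,333920,316876,303968,100.0,94.9,91.0
Yorkshire & Humber,81111,63283,63260,61119,78.0,100.0,96.6
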