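region,total,at_linkage,partial,complete,printed_at_linkage_pct,printed_partial_pct,printed_complete_pct
East Midlands,212395,198085,190681,190679,93.3,96.3,96.3
East of England,574828,474517,462008,462005,82.5,97.4,97.4
London,1208044,1190099,1000246,1000232,98.5,84.0,84.0
North East,218821,208238,175302,175301,95.2,84.2,84.2
North West,767722,733446,660898,656475,95.5,90.1,89.5
South Central,1069029,1069029,1040055,1035340,100.0,97.3,96.8
South East Coast,873765,845650,804428,804367,96.8,95.1,95.1
South West,763658,752735,706818,706817,98.6,93.9,93.9
Wales,564190,503432,485619,451544,89.2,96.5,89.7
West Midlands,716592,716592,662649,633347,100.0,92.5,88.4
Yorkshire & Humber,168321,133559,131448,127256,79.3,98.4,95.3
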