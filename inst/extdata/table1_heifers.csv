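animal_id,age_mo,gestation_mo,bw_kg,bcs,volume_m3,hip_width_mm,withers_height_mm,chest_depth_mm,heart_girth_mm,buttocks_width_mm,calving_date
9209,18.9,2.97,518,2.50,0.582,517,1421,735,2012,526,2021-09-23
9210,18.9,3.20,518,2.75,0.618,530,1366,783,2179,515,2021-09-14
9212,18.8,3.14,474,2.50,0.533,470,1356,725,2004,479,2021-09-16
9213,18.8,2.54,556,3.00,0.617,522,1359,748,2185,529,2021-10-11
9215,18.8,2.74,554,2.75,0.611,552,1431,806,2111,520,2021-10-02
9221,18.9,2.74,532,2.50,0.622,523,1413,763,2222,473,2021-10-09
9224,18.6,3.07,475,2.25,0.534,507,1448,761,1992,509,2021-10-16
9230,18.5,2.97,504,2.25,0.567,482,1410,783,2107,489,2021-09-29
9238,18.4,3.14,564,3.00,0.653,516,1396,794,2260,532,2021-09-18
9239,18.4,2.84,490,2.50,0.556,496,1297,738,2058,521,2021-10-02
9244,18.2,3.00,516,2.75,0.613,509,1326,750,2142,490,2021-10-27
9252,18.0,3.10,418,2.25,0.514,508,1340,701,2020,521,2021-09-24
9270,17.3,2.61,448,2.50,0.536,461,1324,731,1954,481,2021-10-10
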