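terrain,H,D,UNH,NV,HC,DC,UNHC,NVC,reported_area_m2
Bicentenario Park,2677,7917,376,5270,5,162,247,146,115439.10
ESCOM-IPN,5011,5241,204,10829,14,76,134,91,148179.00
Bonito Ecatepec,321,106,41,5350,2,18,74,88,41160.00
Forested area,2258,1429,259,1008,6,55,242,143,37044.08
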