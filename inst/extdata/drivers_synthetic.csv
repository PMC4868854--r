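# SYNTHETIC example driver table (one row per global-change treatment).
# Per-treatment gross ammonification and soil respiration were not printed
# in the source study; these illustrative values follow the package's
# factorial generator defaults (see generate_drivers) with zero noise:
# baseline ammonification 100 ng-N/g/h, respiration 1.8 mg-C/g/h;
# N x1.8 on ammonification, W x1.15 on respiration and x0.9 on
# ammonification, CO2 x1.3 on respiration.
treatment,ammonification_ng_N_g_h,respiration_mg_C_g_h
CTRL,100,1.8
N,180,1.8
W,90,2.07
NW,162,2.07
CO2,100,2.34
CO2N,180,2.34
CO2W,90,2.691
CO2NW,162,2.691
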