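group,member_areas,spine_count,neural_density,rostrocaudal_mm
V1g,A001,1500,160000,2.0
V2g,A002;A003,2100,140000,4.5
AUDg,A004,2600,120000,6.0
S1g,A005;A006,3200,105000,8.5
PPCg,A007,4300,90000,11.0
TEOg,A008;A009,5200,80000,13.5
PFCg,A010,6900,65000,17.0
PMVg,A011;A012,8200,56000,19.5
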