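element,value,unit,source
La,31.1,mg/kg,Gromet et al. (1984) GCA 48:2469-2482
Ce,66.7,mg/kg,Gromet et al. (1984) GCA 48:2469-2482
Pr,7.9,mg/kg,Haskin et al. (1968) interpolation adopted for NASC
Nd,27.4,mg/kg,Gromet et al. (1984) GCA 48:2469-2482
Sm,5.59,mg/kg,Gromet et al. (1984) GCA 48:2469-2482
Eu,1.18,mg/kg,Gromet et al. (1984) GCA 48:2469-2482
Gd,5.5,mg/kg,Haskin et al. (1968) interpolation adopted for NASC
Tb,0.85,mg/kg,Gromet et al. (1984) GCA 48:2469-2482
Dy,5.54,mg/kg,Haskin et al. (1968) interpolation adopted for NASC
Ho,1.04,mg/kg,Gromet et al. (1984) GCA 48:2469-2482
Er,3.28,mg/kg,Gromet et al. (1984) GCA 48:2469-2482
Tm,0.50,mg/kg,Haskin et al. (1968) interpolation adopted for NASC
Yb,3.06,mg/kg,Gromet et al. (1984) GCA 48:2469-2482
Lu,0.456,mg/kg,Gromet et al. (1984) GCA 48:2469-2482
Y,35,mg/kg,Gromet et al. (1984) GCA 48:2469-2482
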