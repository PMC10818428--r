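element,value,unit,source
La,31,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Ce,63,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Pr,7.1,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Nd,27,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Sm,4.7,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Eu,1.0,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Gd,4.0,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Tb,0.7,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Dy,3.9,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Ho,0.83,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Er,2.3,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Tm,0.30,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Yb,2.0,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Lu,0.31,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Y,21,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
As,4.8,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Cr,92,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
V,97,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Pb,17,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Ni,47,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Mn,775,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3 (from MnO 0.10 wt%)
Ba,628,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Cd,0.09,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Cu,28,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Mo,1.1,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Co,17.3,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Hg,0.05,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
Zn,67,mg/kg,Rudnick & Gao (2003) Treatise on Geochemistry vol. 3
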