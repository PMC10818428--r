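element,tr,rfd,csf,source
La,1,0.02,3.2e-12,REY Tr per Hakanson-type coefficients; common REY oral RfD/CSF
Ce,1,0.02,3.2e-12,REY Tr per Hakanson-type coefficients; common REY oral RfD/CSF
Pr,5,0.02,3.2e-12,REY Tr per Hakanson-type coefficients; common REY oral RfD/CSF
Nd,2,0.02,3.2e-12,REY Tr per Hakanson-type coefficients; common REY oral RfD/CSF
Sm,5,0.02,3.2e-12,REY Tr per Hakanson-type coefficients; common REY oral RfD/CSF
Eu,10,0.02,3.2e-12,REY Tr per Hakanson-type coefficients; common REY oral RfD/CSF
Gd,5,0.02,3.2e-12,REY Tr per Hakanson-type coefficients; common REY oral RfD/CSF
Tb,10,0.02,3.2e-12,REY Tr per Hakanson-type coefficients; common REY oral RfD/CSF
Dy,5,0.02,3.2e-12,REY Tr per Hakanson-type coefficients; common REY oral RfD/CSF
Ho,10,0.02,3.2e-12,REY Tr per Hakanson-type coefficients; common REY oral RfD/CSF
Er,5,0.02,3.2e-12,REY Tr per Hakanson-type coefficients; common REY oral RfD/CSF
Tm,10,0.02,3.2e-12,REY Tr per Hakanson-type coefficients; common REY oral RfD/CSF
Yb,5,0.02,3.2e-12,REY Tr per Hakanson-type coefficients; common REY oral RfD/CSF
Lu,20,0.02,3.2e-12,REY Tr per Hakanson-type coefficients; common REY oral RfD/CSF
Y,2,0.02,3.2e-12,REY Tr per Hakanson-type coefficients; common REY oral RfD/CSF
As,10,3.0e-4,1.5,Hakanson (1980) Tr; USEPA IRIS oral RfD/CSF for inorganic As
Cd,30,1.0e-3,6.1,Hakanson (1980) Tr; IRIS oral RfD; conventional oral slope factor
Cr,2,3.0e-3,0.5,Hakanson (1980) Tr; IRIS Cr(VI) oral RfD; NJDEP-derived oral slope factor
Pb,5,3.5e-3,8.5e-3,Hakanson (1980) Tr; conventional oral RfD; CalEPA oral slope factor
Ni,5,2.0e-2,0.84,Hakanson (1980) Tr; IRIS oral RfD; conventional slope factor
Co,5,3.0e-4,9.8,Hakanson (1980) Tr; PPRTV oral RfD; conventional slope factor
Cu,5,4.0e-2,NA,Hakanson (1980) Tr; USEPA HEAST oral RfD; no oral CSF
Hg,40,3.0e-4,NA,Hakanson (1980) Tr; IRIS Hg(II) oral RfD; no oral CSF
Mn,1,4.6e-2,NA,Hakanson (1980) Tr; IRIS-derived soil RfD; no oral CSF
Zn,1,3.0e-1,NA,Hakanson (1980) Tr; IRIS oral RfD; no oral CSF
V,NA,5.04e-3,NA,No Hakanson Tr; USEPA RSL oral RfD; no oral CSF
Ba,NA,2.0e-1,NA,No Hakanson Tr; IRIS oral RfD; no oral CSF
Mo,NA,5.0e-3,NA,No Hakanson Tr; IRIS oral RfD; no oral CSF
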