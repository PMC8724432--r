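chromophore,wavelength_nm,epsilon
Hb,660,7.4294e-04
HbO2,660,7.3590e-05
Hb,750,3.2357e-04
HbO2,750,1.2956e-04
Hb,840,1.5958e-04
HbO2,840,2.4361e-04
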