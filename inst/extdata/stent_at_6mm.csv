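stent,area_mm2,dS_mm,dL_mm
NiTi 1a,5.7,2.2,3.3
NiTi 2,5,1.5,4.1
NiTi 3a,5.7,1.7,4.2
NiTi 3b,7.7,1.8,5.5
CoCr,7.1,2.7,3.4
Polymer,4.0,1.9,2.6
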