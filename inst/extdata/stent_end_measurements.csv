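stent,area_pharynx_mm2,area_isthmus_mm2,area_avg_mm2,dL_pharynx_mm,dS_pharynx_mm,dL_isthmus_mm,dS_isthmus_mm,D1_avg_mm,D2_avg_mm
NiTi 1a,9.8,1.5,6,4.4,2.9,1.9,1,0.9,1.1
NiTi 2,13.8,4.7,9.3,4.4,4,4.1,1.5,1.3,1.5
NiTi 3a,10,1.9,4.9,5.6,2.3,3.1,0.8,0.5,0.9
NiTi 3b,15.1,7.1,10,5.3,3.6,5.3,1.7,0.9,1.4
CoCr,6,3.8,6.6,3.9,2,3.3,1.5,0.9,1.4
Polymer,3.2,2.9,3.5,2.2,1.8,2.1,1.8,0.7,1
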