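stent,length_mm,dist_pharynx_mm,dist_isthmus_mm,cartilaginous_length_mm
NiTi 1a,13.1,6.2,0.3,19.6
NiTi 2,15.8,-3,5.4,18.2
NiTi 3a,15,7.8,-1.7,21.1
NiTi 3b,15.7,8.8,3.5,28
CoCr,13.2,9.7,-0.6,22.3
Polymer,19.9,12,-6.8,25.1
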