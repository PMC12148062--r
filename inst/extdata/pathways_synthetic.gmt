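opioid_signaling_synthetic	synthetic fixture	Pdyn	Oprk1	Pomc	Oprd1
bbb_junction_synthetic	synthetic fixture	Cldn5	Ocln	Tjp1	Cdh5
astrocyte_markers_synthetic	synthetic fixture	Gfap	Aqp4	Slc1a3
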