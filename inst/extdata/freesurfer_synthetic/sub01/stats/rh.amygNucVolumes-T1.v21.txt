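Lateral-nucleus 655.101990
Basal-nucleus 441.220001
Accessory-Basal-nucleus 257.890015
Anterior-amygdaloid-area-AAA 57.110001
Central-nucleus 46.330002
Medial-nucleus 21.230000
Cortical-nucleus 26.440001
Corticoamygdaloid-transitio 178.110001
Paralaminar-nucleus 52.330002
Whole_amygdala 1735.781982
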