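Lateral-nucleus 640.220093
Basal-nucleus 430.109985
Accessory-Basal-nucleus 250.320007
Anterior-amygdaloid-area-AAA 55.310001
Central-nucleus 44.220001
Medial-nucleus 20.110001
Cortical-nucleus 25.330000
Corticoamygdaloid-transitio 172.220001
Paralaminar-nucleus 50.110001
Whole_amygdala 1687.949951
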