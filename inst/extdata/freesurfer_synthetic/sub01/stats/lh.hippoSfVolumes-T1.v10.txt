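Hippocampal_tail 521.304199
subiculum-body 242.112091
CA1-body 135.420105
subiculum-head 178.911804
hippocampal-fissure 150.208801
presubiculum-head 131.204102
CA1-head 498.702881
presubiculum-body 66.410202
parasubiculum 59.123100
molecular_layer_HP-head 330.219910
molecular_layer_HP-body 208.554199
GC-ML-DG-head 160.330902
CA3-body 84.221107
GC-ML-DG-body 101.228104
CA4-head 140.221893
CA4-body 99.860901
fimbria 73.551102
CA3-head 118.220901
HATA 57.881001
Whole_hippocampal_body 1162.312012
Whole_hippocampal_head 1650.224121
Whole_hippocampus 3351.220215
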