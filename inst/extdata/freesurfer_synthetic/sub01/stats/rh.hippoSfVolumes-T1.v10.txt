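Hippocampal_tail 538.110291
subiculum-body 250.330307
CA1-body 139.882904
subiculum-head 182.445602
hippocampal-fissure 144.320206
presubiculum-head 128.778503
CA1-head 510.339905
presubiculum-body 64.221001
parasubiculum 57.990002
molecular_layer_HP-head 338.450012
molecular_layer_HP-body 214.220901
GC-ML-DG-head 165.101898
CA3-body 88.430000
GC-ML-DG-body 104.550003
CA4-head 143.770996
CA4-body 102.221001
fimbria 70.221001
CA3-head 121.334999
HATA 59.202000
Whole_hippocampal_body 1190.443115
Whole_hippocampal_head 1685.220093
Whole_hippocampus 3422.109863
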