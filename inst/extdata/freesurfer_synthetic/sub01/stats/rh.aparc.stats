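# Table of FreeSurfer cortical parcellation anatomical statistics
# SYNTHETIC FIXTURE: miniature rh.aparc.stats for parser tests; values invented.
# subjectname sub01
# hemi rh
# NTableCols 10
# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg ThickStd MeanCurv GausCurv FoldInd CurvInd
bankssts                                 1388    960   2544  2.488 0.399     0.116     0.027       10     1.4
caudalanteriorcingulate                  1021    690   2050  2.688 0.571     0.133     0.030        9     1.3
entorhinal                                598    410   1876  3.200 0.688     0.119     0.040        6     1.0
fusiform                                 4555   3140   9377  2.790 0.491     0.127     0.031       41     5.7
inferiortemporal                         4801   3305  10190  2.741 0.545     0.121     0.030       43     6.1
parahippocampal                          1090    709   2080  2.770 0.595     0.097     0.021        8     1.0
precuneus                                5890   4030   9901  2.410 0.433     0.127     0.028       50     6.7
superiortemporal                         5598   3810  11190  2.805 0.498     0.108     0.023       44     6.0
temporalpole                              701    488   2244  3.588 0.690     0.141     0.049        9     1.5
insula                                   2955   1960   6198  3.001 0.680     0.118     0.034       25     4.0
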