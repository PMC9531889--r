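# Table of FreeSurfer cortical parcellation anatomical statistics
# SYNTHETIC FIXTURE: miniature lh.aparc.stats for parser tests; values invented.
# subjectname sub01
# hemi lh
# NTableCols 10
# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg ThickStd MeanCurv GausCurv FoldInd CurvInd
bankssts                                 1432    989   2610  2.512 0.412     0.114     0.025       11     1.5
caudalanteriorcingulate                   998    672   2001  2.701 0.580     0.131     0.031        9     1.2
entorhinal                                612    421   1905  3.310 0.702     0.121     0.042        6     1.1
fusiform                                 4620   3190   9512  2.801 0.498     0.129     0.033       42     5.9
inferiortemporal                         4890   3370  10388  2.750 0.551     0.122     0.031       44     6.3
parahippocampal                          1109    722   2118  2.790 0.601     0.098     0.022        8     1.0
precuneus                                5801   3980   9790  2.401 0.430     0.128     0.029       49     6.6
superiortemporal                         5710   3890  11411  2.820 0.501     0.109     0.024       45     6.1
temporalpole                              720    501   2290  3.612 0.702     0.144     0.051        9     1.6
insula                                   3001   1990   6305  3.010 0.688     0.119     0.035       25     4.1
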