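# Title Segmentation Statistics
# generating_program mri_segstats
# SYNTHETIC FIXTURE: hand-written miniature aseg.stats in the FreeSurfer 6
# dialect, for parser tests only. Values are invented.
# subjectname sub01
# Measure BrainSeg, BrainSegVol, Brain Segmentation Volume, 1143267.000000, mm^3
# Measure TotalGray, TotalGrayVol, Total gray matter volume, 644505.428984, mm^3
# Measure Cortex, lhCortexVol, Left hemisphere cortical gray matter volume, 234583.565169, mm^3
# Measure Cortex, rhCortexVol, Right hemisphere cortical gray matter volume, 235214.112208, mm^3
# Measure CerebralWhiteMatter, lhCerebralWhiteMatterVol, Left hemisphere cerebral white matter volume, 215400.500000, mm^3
# Measure CerebralWhiteMatter, rhCerebralWhiteMatterVol, Right hemisphere cerebral white matter volume, 216100.250000, mm^3
# Measure EstimatedTotalIntraCranialVol, eTIV, Estimated Total Intracranial Volume, 1557160.869617, mm^3
# NTableCols 10
# ColHeaders Index SegId NVoxels Volume_mm3 StructName normMean normStdDev normMin normMax normRange
  1   4      7534     7938.9  Left-Lateral-Ventricle            25.1  12.2  5  85  80
  2   5       234      268.6  Left-Inf-Lat-Vent                 40.2  13.1  10  80  70
  3   7     13642    14165.4  Left-Cerebellum-White-Matter      85.5   7.1  35 105  70
  4   8     51478    52556.9  Left-Cerebellum-Cortex            62.8  10.3  15  98  83
  5  10      7204     7405.1  Left-Thalamus-Proper              88.1   8.9  30 108  78
  6  11      3481     3598.2  Left-Caudate                      75.2   7.6  42 100  58
  7  12      4962     5102.7  Left-Putamen                      81.4   6.5  50 105  55
  8  13      1787     1843.5  Left-Pallidum                     95.7   4.9  70 115  45
  9  14      1021     1091.3  3rd-Ventricle                     34.5  13.8  10  75  65
 10  15      1724     1838.4  4th-Ventricle                     28.9  12.0   8  70  62
 11  16     20541    21114.8  Brain-Stem                        82.3   9.4  25 110  85
 12  17      3912     4000.0  Left-Hippocampus                  70.1   8.0  30  98  68
 13  18      1603     1654.9  Left-Amygdala                     71.9   6.8  40  95  55
 14  24       987     1055.7  CSF                               45.3  12.5  15  90  75
 15  26       573      589.2  Left-Accumbens-area               73.2   5.4  50  92  42
 16  43      6912     7261.3  Right-Lateral-Ventricle           25.9  12.6  5  86  81
 17  44       201      230.4  Right-Inf-Lat-Vent                41.0  13.5  11  82  71
 18  46     13201    13702.6  Right-Cerebellum-White-Matter     85.9   7.0  36 106  70
 19  47     52013    53120.2  Right-Cerebellum-Cortex           62.5  10.5  15  99  84
 20  50      3522     3641.8  Right-Caudate                     75.8   7.4  43 101  58
 21  51      5048     5190.3  Right-Putamen                     81.0   6.7  49 104  55
 22  52      1801     1858.0  Right-Pallidum                    95.3   5.0  69 114  45
 23  53      4055     4147.6  Right-Hippocampus                 69.8   8.2  29  97  68
 24  54      1671     1725.2  Right-Amygdala                    71.4   7.0  39  96  57
 25  58       602      618.8  Right-Accumbens-area              72.8   5.6  49  93  44
 26 251       890      921.4  CC_Posterior                     100.2   6.1  75 118  43
 27 252       412      430.9  CC_Mid_Posterior                  98.7   7.3  70 117  47
 28 253       445      462.1  CC_Central                        99.1   7.0  72 116  44
 29 254       460      477.8  CC_Mid_Anterior                   99.5   6.8  71 117  46
 30 255       810      842.3  CC_Anterior                      101.0   6.3  74 119  45
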