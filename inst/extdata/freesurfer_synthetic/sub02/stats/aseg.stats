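# Title Segmentation Statistics
# SYNTHETIC FIXTURE: second subject, aseg only (no aparc/subfield runs), to
# exercise sparse-table handling. Values are invented.
# subjectname sub02
# Measure BrainSeg, BrainSegVol, Brain Segmentation Volume, 1098210.000000, mm^3
# Measure TotalGray, TotalGrayVol, Total gray matter volume, 622108.221000, mm^3
# Measure EstimatedTotalIntraCranialVol, eTIV, Estimated Total Intracranial Volume, 1450310.220000, mm^3
# ColHeaders Index SegId NVoxels Volume_mm3 StructName normMean normStdDev normMin normMax normRange
  1   4      8211     8540.2  Left-Lateral-Ventricle            24.8  12.4  5  84  79
  2  17      3644     3721.5  Left-Hippocampus                  70.5   7.8  31  97  66
  3  43      7980     8321.8  Right-Lateral-Ventricle           25.2  12.7  5  85  80
  4  53      3700     3788.1  Right-Hippocampus                 70.2   8.1  30  96  66
  5  14       998     1033.2  3rd-Ventricle                     34.1  13.6  10  74  64
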