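# Default HU <-> relative electron density calibration curve.
# Nodes pin the tissue electron densities used for mask provenance onto the
# package's HU thresholds (air, lung, fat window, water, bone).
# HU    RED
-1000   0.00
-740    0.26
-100    0.93
-20     0.98
0       1.00
150     1.20
1500    2.00
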