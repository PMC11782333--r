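patient_id,visit,hlpr,osi_area_percent
P1,3d,0.31,1.51
P1,3w,0.34,15.98
P1,1y,0.59,31.79
P2,3d,0.18,0.71
P2,3w,1.13,37.64
P2,1y,0.91,19.17
P3,3d,0.33,17.1
P3,3w,0.23,17.49
P3,1y,0.49,34.09
P4,3d,0.71,9.43
P4,3w,0.36,35.57
P4,1y,0.75,27.27
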