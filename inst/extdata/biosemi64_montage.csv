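channel,x,y
Fp1,-0.496189,1.527114
AF7,-0.943808,1.299041
AF3,-0.54583,1.170536
F1,-0.326906,0.809121
F3,-0.659023,0.813825
F5,-0.987913,0.858779
F7,-1.299041,0.943808
FT7,-1.527114,0.496189
FC5,-1.173172,0.450338
FC3,-0.770517,0.409691
FC1,-0.394923,0.394923
C1,-0.401426,-0.0
C3,-0.802851,-0.0
C5,-1.204277,-0.0
T7,-1.605703,-0.0
TP7,-1.527114,-0.496189
CP5,-1.173172,-0.450338
CP3,-0.770517,-0.409691
CP1,-0.394923,-0.394923
P1,-0.326906,-0.809121
P3,-0.659023,-0.813825
P5,-0.987913,-0.858779
P7,-1.299041,-0.943808
P9,-1.623801,-1.179761
PO7,-0.943808,-1.299041
PO3,-0.54583,-1.170536
O1,-0.496189,-1.527114
Iz,0.0,-2.007129
Oz,0.0,-1.605703
POz,0.0,-1.204277
Pz,0.0,-0.802851
CPz,0.0,-0.401426
Fpz,0.0,1.605703
Fp2,0.496189,1.527114
AF8,0.943808,1.299041
AF4,0.54583,1.170536
AFz,0.0,1.204277
Fz,0.0,0.802851
F2,0.326906,0.809121
F4,0.659023,0.813825
F6,0.987913,0.858779
F8,1.299041,0.943808
FT8,1.527114,0.496189
FC6,1.173172,0.450338
FC4,0.770517,0.409691
FC2,0.394923,0.394923
FCz,0.0,0.401426
Cz,0.0,0.0
C2,0.401426,0.0
C4,0.802851,0.0
C6,1.204277,0.0
T8,1.605703,0.0
TP8,1.527114,-0.496189
CP6,1.173172,-0.450338
CP4,0.770517,-0.409691
CP2,0.394923,-0.394923
P2,0.326906,-0.809121
P4,0.659023,-0.813825
P6,0.987913,-0.858779
P8,1.299041,-0.943808
P10,1.623801,-1.179761
PO8,0.943808,-1.299041
PO4,0.54583,-1.170536
O2,0.496189,-1.527114
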