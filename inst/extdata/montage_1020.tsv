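label	incl_deg	az_deg
Fp1	90	-18
Fp2	90	18
F3	65.1504	-31.9961
F4	65.1504	31.9961
C3	45	-90
C4	45	90
P3	65.1504	-148.0039
P4	65.1504	148.0039
O1	90	-162
O2	90	162
F7	90	-54
F8	90	54
T3	90	-90
T4	90	90
T5	90	-126
T6	90	126
Fz	45	0
Cz	0	0
Pz	45	180
A1	112	-95
A2	112	95
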