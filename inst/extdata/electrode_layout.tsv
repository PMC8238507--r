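electrode	x	y
Fp1	-0.1252	0.8553
Fpz	0	0.8625
Fp2	0.1252	0.8553
AF7	-0.43	0.6189
AF3	-0.1433	0.6653
AFz	0	0.6708
AF4	0.1433	0.6653
AF8	0.43	0.6189
F7	-0.6221	0.4109
F5	-0.4665	0.4421
F3	-0.311	0.4631
F1	-0.1555	0.4752
Fz	0	0.4792
F2	0.1555	0.4752
F4	0.311	0.4631
F6	0.4665	0.4421
F8	0.6221	0.4109
FT7	-0.6526	0.2466
FC5	-0.4894	0.2653
FC3	-0.3263	0.2778
FC1	-0.1631	0.2851
FCz	0	0.2875
FC2	0.1631	0.2851
FC4	0.3263	0.2778
FC6	0.4894	0.2653
FT8	0.6526	0.2466
T7	-0.6673	0.0822
C5	-0.5005	0.0884
C3	-0.3336	0.0926
C1	-0.1668	0.095
Cz	0	0.0958
C2	0.1668	0.095
C4	0.3336	0.0926
C6	0.5005	0.0884
T8	0.6673	0.0822
TP7	-0.6673	-0.0822
CP5	-0.5005	-0.0884
CP3	-0.3336	-0.0926
CP1	-0.1668	-0.095
CPz	0	-0.0958
CP2	0.1668	-0.095
CP4	0.3336	-0.0926
CP6	0.5005	-0.0884
TP8	0.6673	-0.0822
P9	-0.8157	-0.2202
P7	-0.6526	-0.2466
P5	-0.4894	-0.2653
P3	-0.3263	-0.2778
P1	-0.1631	-0.2851
Pz	0	-0.2875
P2	0.1631	-0.2851
P4	0.3263	-0.2778
P6	0.4894	-0.2653
P8	0.6526	-0.2466
P10	0.8157	-0.2202
PO7	-0.4665	-0.4421
PO3	-0.1555	-0.4752
POz	0	-0.4792
PO4	0.1555	-0.4752
PO8	0.4665	-0.4421
O1	-0.1433	-0.6653
Oz	0	-0.6708
O2	0.1433	-0.6653
Iz	0	-0.8625
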