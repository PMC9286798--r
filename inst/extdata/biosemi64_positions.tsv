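label	x	y
Fp1	-0.4962	1.5271
AF7	-0.9438	1.2990
AF3	-0.5458	1.1705
F1	-0.3269	0.8091
F3	-0.6590	0.8138
F5	-0.9879	0.8588
F7	-1.2990	0.9438
FT7	-1.5271	0.4962
FC5	-1.1732	0.4503
FC3	-0.7705	0.4097
FC1	-0.3949	0.3949
C1	-0.4014	0.0000
C3	-0.8029	0.0000
C5	-1.2043	0.0000
T7	-1.6057	0.0000
TP7	-1.5271	-0.4962
CP5	-1.1732	-0.4503
CP3	-0.7705	-0.4097
CP1	-0.3949	-0.3949
P1	-0.3269	-0.8091
P3	-0.6590	-0.8138
P5	-0.9879	-0.8588
P7	-1.2990	-0.9438
P9	-1.6238	-1.1798
PO7	-0.9438	-1.2990
PO3	-0.5458	-1.1705
O1	-0.4962	-1.5271
Iz	0.0000	-2.0071
Oz	0.0000	-1.6057
POz	0.0000	-1.2043
Pz	0.0000	-0.8029
CPz	0.0000	-0.4014
Fpz	0.0000	1.6057
Fp2	0.4962	1.5271
AF8	0.9438	1.2990
AF4	0.5458	1.1705
AFz	0.0000	1.2043
Fz	0.0000	0.8029
F2	0.3269	0.8091
F4	0.6590	0.8138
F6	0.9879	0.8588
F8	1.2990	0.9438
FT8	1.5271	0.4962
FC6	1.1732	0.4503
FC4	0.7705	0.4097
FC2	0.3949	0.3949
FCz	0.0000	0.4014
Cz	0.0000	0.0000
C2	0.4014	0.0000
C4	0.8029	0.0000
C6	1.2043	0.0000
T8	1.6057	0.0000
TP8	1.5271	-0.4962
CP6	1.1732	-0.4503
CP4	0.7705	-0.4097
CP2	0.3949	-0.3949
P2	0.3269	-0.8091
P4	0.6590	-0.8138
P6	0.9879	-0.8588
P8	1.2990	-0.9438
P10	1.6238	-1.1798
PO8	0.9438	-1.2990
PO4	0.5458	-1.1705
O2	0.4962	-1.5271
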