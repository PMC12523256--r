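parameter	correct	accuracy	precision	recall	f1
EPE	87	0.989	0.989	1.000	0.994
Histologic Subtype	78	0.886	0.897	0.987	0.940
Lymph Nodes with Metastasis	88	1.000	1.000	1.000	1.000
M-Stage	61	0.693	0.984	0.701	0.819
N-Stage	88	1.000	1.000	1.000	1.000
Number of Lymph Nodes examined	88	1.000	1.000	1.000	1.000
Percentage of Secondary Gleason Pattern	59	0.670	0.967	0.686	0.803
Perineural Invasion	88	1.000	1.000	1.000	1.000
Primary Gleason Pattern	87	0.989	1.000	0.989	0.994
Resection Margins	87	0.989	1.000	0.989	0.994
Secondary Gleason Pattern	87	0.989	1.000	0.989	0.994
SVI	88	1.000	1.000	1.000	1.000
PSA	87	0.989	0.989	1.000	0.994
T-Stage	88	1.000	1.000	1.000	1.000
Tertiary Gleason Pattern	75	0.852	1.000	0.852	0.920
WHO Grade Group	84	0.955	1.000	0.955	0.977
Overall (micro)	1320	0.938	0.990	0.947	0.968
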