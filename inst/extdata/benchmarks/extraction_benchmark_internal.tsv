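parameter	correct	accuracy	precision	recall	f1
EPE	148	0.987	1.000	0.987	0.993
Histologic Subtype	139	0.927	1.000	0.927	0.962
Lymph Nodes with Metastasis	149	0.993	0.993	1.000	0.997
M-Stage	150	1.000	1.000	1.000	1.000
N-Stage	149	0.993	0.993	1.000	0.997
Number of Lymph Nodes examined	148	0.987	0.993	0.993	0.993
Percentage of Secondary Gleason Pattern	136	0.907	0.971	0.932	0.951
Perineural Invasion	147	0.980	1.000	0.980	0.990
Primary Gleason Pattern	148	0.987	1.000	0.987	0.993
Resection Margins	148	0.987	1.000	0.987	0.993
Secondary Gleason Pattern	148	0.987	1.000	0.987	0.993
SVI	150	1.000	1.000	1.000	1.000
PSA	140	0.933	0.933	1.000	0.966
T-Stage	144	0.960	0.980	0.980	0.980
Tertiary Gleason Pattern	149	0.993	1.000	0.993	0.997
WHO Grade Group	141	0.940	1.000	0.940	0.969
Overall (micro)	2334	0.973	0.992	0.981	0.986
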