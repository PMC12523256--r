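class	tp	fp	fn	precision	recall	f1
IIB	33	1	2	0.971	0.943	0.957
IIC	13	2	1	0.867	0.929	0.897
IIIA	7	1	0	0.875	1.000	0.933
IIIB	38	4	0	0.905	1.000	0.950
IIIC	14	0	0	1.000	1.000	1.000
IVA	12	1	0	0.923	1.000	0.960
Unknown	22	2	8	0.917	0.733	0.815
Overall (macro)	NA	NA	NA	0.922	0.944	0.930
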