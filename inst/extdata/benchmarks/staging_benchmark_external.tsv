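class	tp	fp	fn	precision	recall	f1
IIA	3	1	0	0.750	1.000	0.857
IIB	13	2	2	0.867	0.867	0.867
IIC	6	1	0	0.857	1.000	0.923
IIIB	31	4	0	0.886	1.000	0.939
IIIC	8	2	0	0.800	1.000	0.889
IVA	9	2	0	0.818	1.000	0.900
Unknown	5	1	11	0.833	0.313	0.455
Overall (macro)	NA	NA	NA	0.830	0.883	0.833
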