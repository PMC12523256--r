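dataset	stage	x	n	pct	ci_lower_pct	ci_upper_pct
internal	IIB	35	122	28.7	21.4	37.3
internal	IIC	14	122	11.5	7.0	18.3
internal	IIIA	7	122	5.7	2.8	11.4
internal	IIIB	38	122	31.1	23.6	39.8
internal	IIIC	15	122	12.3	7.6	19.3
internal	IVA	13	122	10.7	6.3	17.4
external	IIA	3	72	4.2	1.4	11.5
external	IIB	15	72	20.8	13.1	31.6
external	IIC	6	72	8.3	3.9	17.0
external	IIIB	31	72	43.1	32.3	54.6
external	IIIC	8	72	11.1	5.7	20.4
external	IVA	9	72	12.5	6.7	22.1
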