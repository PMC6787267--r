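module	n_pairs	dispersal_limitation	drift	variable_selection	homogenizing_selection	stochastic_total	deterministic_total
SL2750	45	2.22	53.33	44.45	0.00	55.55	44.45
CF2550	45	68.89	0.00	31.11	0.00	68.89	31.11
MF2300	45	0.00	73.33	26.67	0.00	73.33	26.67
DBF1780	45	2.22	35.56	60.00	2.22	37.78	62.22
EBF1030	28	21.43	46.43	32.14	0.00	67.86	32.14
SL2750-CF2550	100	1.00	6.00	93.00	0.00	7.00	93.00
SL2750-MF2300	100	3.00	14.00	83.00	0.00	17.00	83.00
SL2750-DBF1780	100	38.00	14.00	48.00	0.00	52.00	48.00
SL2750-EBF1030	80	50.00	15.00	35.00	0.00	65.00	35.00
CF2550-MF2300	100	0.00	46.00	54.00	0.00	46.00	54.00
CF2550-DBF1780	100	32.00	5.00	70.00	0.00	37.00	70.00
CF2550-EBF1030	80	25.00	5.00	70.00	0.00	30.00	70.00
MF2300-DBF1780	100	22.00	16.00	61.00	1.00	38.00	62.00
MF2300-EBF1030	80	26.25	5.00	68.75	0.00	31.25	68.75
DBF1780-EBF1030	80	58.75	1.25	40.00	0.00	60.00	40.00
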