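sample	locus_id	total_reads	alt_reads	qual_central	qual_flank_min
UV	UBP7	100000	60000	45	38
UV	PBP1	100000	60500	44	37
UV	SGO1	100000	59600	45	38
UV	YNL058C	100000	60200	46	39
UV	BCS1	100000	61000	45	38
UV	GSH1	100000	30000	44	36
UV	ART5	100000	20000	45	38
UV	GDH1_S16F	100000	2000	45	38
UV	NRG1	100000	4000	45	37
UV	TOF2	100000	600	44	38
UV	DOP1	100000	500	45	38
R1	UBP7	100000	72000	45	38
R1	PBP1	100000	45000	44	37
R1	SGO1	100000	44000	45	38
R1	YNL058C	100000	46000	46	39
R1	BCS1	100000	45500	45	38
R1	GSH1	100000	42000	44	36
R1	ART5	100000	55000	45	38
R1	GDH1_S16F	100000	9000	45	38
R1	NRG1	100000	1500	45	37
R1	TOF2	100000	8000	44	38
R1	DOP1	100000	400	45	38
R3	UBP7	100000	88000	45	38
R3	PBP1	100000	24000	44	37
R3	SGO1	100000	23000	45	38
R3	YNL058C	100000	25000	46	39
R3	BCS1	100000	24500	45	38
R3	GSH1	100000	54000	44	36
R3	ART5	100000	78000	45	38
R3	GDH1_S16F	100000	30000	45	38
R3	NRG1	100000	2000	45	37
R3	TOF2	100000	2000	44	38
R3	DOP1	100000	600	45	38
R5	UBP7	100000	80000	45	38
R5	PBP1	100000	10000	44	37
R5	SGO1	100000	9000	45	38
R5	YNL058C	100000	11000	46	39
R5	BCS1	100000	10500	45	38
R5	GSH1	100000	50000	44	36
R5	ART5	100000	74000	45	38
R5	GDH1_S16F	100000	52000	45	38
R5	NRG1	100000	11000	45	37
R5	TOF2	100000	500	44	38
R5	DOP1	100000	700	45	38
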