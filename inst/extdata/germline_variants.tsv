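case_id	chrom	pos	ref	alt	gene	transcript_id	protein_change	total_depth	vaf_tumor	vaf_normal	clinical_significance
YMC54	2	29449820	G	A	ALK	NM_004304.4	p.T1012M	637	48.51%	60.36%	Benign
YMC7	2	29449820	G	A	ALK	NM_004304.4	p.T1012M	208	55.77%	43.83%	Benign
YMC70	2	29449820	G	A	ALK	NM_004304.4	p.T1012M	755	52.58%	57.85%	Benign
SKW18	2	29519923	G	A	ALK	NM_004304.4	p.L550F	155	38.06%	55.39%	VUS
YMC13	5	112177778	A	C	APC	NM_001127511.2	p.K2145Q	151	52.32%	33.74%	Benign
YMC24	5	112178865	G	A	APC	NM_001127511.2	p.R2507H	1142	47.90%	49.52%	VUS
SKW38	5	112176548	G	C	APC	NM_001127511.2	p.A1735P	628	45.86%	47.30%	VUS
SKW21	5	112173895	A	C	APC	NM_001127511.2	p.E850D	147	55.78%	50.93%	Benign
YMC29	16	68867247	G	A	CDH1	NM_004360.4	p.V832M	1337	52.21%	49.75%	Likely pathogenic
YMC37	16	68867247	G	A	CDH1	NM_004360.4	p.V832M	1498	50.73%	46.41%	Likely pathogenic
SKW16	16	68856080	C	G	CDH1	NM_004360.4	p.L630V	928	43.74%	40.61%	Benign
SKW15	16	68856080	C	G	CDH1	NM_004360.4	p.L630V	827	49.33%	71.46%	Benign
YMC53	3	37053562	C	T	MLH1	NM_000249.3	p.R217C	1397	46.96%	50.40%	VUS
YMC55	3	37042521	T	G	MLH1	NM_000249.3	p.S95A	233	39.06%	30.52%	VUS
YMC6	3	37067240	T	A	MLH1	NM_000249.3	p.V384D	578	48.79%	44.85%	Benign
YMC70	3	37067240	T	A	MLH1	NM_000249.3	p.V384D	547	51.55%	47.99%	Benign
YMC14	3	37053562	C	T	MLH1	NM_000249.3	p.R217C	1409	45.71%	51.65%	VUS
YMC22	3	37067240	T	A	MLH1	NM_000249.3	p.V384D	862	99.54%	100%	Benign
YMC3	3	37090506	C	A	MLH1	NM_000249.3	p.Q701K	369	51.49%	41.29%	Benign
YMC4	3	37089022	C	G	MLH1	NM_000249.3	p.L582V	364	48.63%	57.47%	VUS
YMC37	3	37053562	C	T	MLH1	NM_000249.3	p.R217C	1315	49.20%	49.76%	VUS
YMC48	3	37067240	T	A	MLH1	NM_000249.3	p.V384D	899	43.38%	44.61%	Benign
SKW31	3	37053562	C	T	MLH1	NM_000249.3	p.R217C	294	55.78%	39.71%	VUS
YMC66	2	47656972	C	T	MSH2	NM_000251.2	p.L390F	197	56.85%	52.78%	Benign
YMC15	2	47656972	C	T	MSH2	NM_000251.2	p.L390F	1281	46.68%	79.62%	Benign
YMC28	2	47630344	C	A	MSH2	NM_000251.2	p.P5Q	231	53.25%	86.79%	VUS
YMC5	2	47637371	A	G	MSH2	NM_000251.2	p.I169V	711	51.34%	45.12%	Likely benign
YMC48	2	47656972	C	T	MSH2	NM_000251.2	p.L390F	692	51.30%	53.31%	Benign
SKW41	2	47703564	G	A	MSH2	NM_000251.2	p.M688I	993	52.57%	50.83%	VUS
SKW40	17	7578209	G	A	TP53	NM_000546.5	p.H214Y	168	39.29%	59.58%	VUS
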