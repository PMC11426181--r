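# Published descriptive summary of the 2200 FAERS reports (2013Q2-2023Q4)
# with trametinib as primary suspect: count and printed percent per row.
# Denominators: year/sex/age/reporter/country/route = 2200 reports;
# outcome = 2789 outcome codes; onset = 1589 onset entries.
category	label	count	percent
year	2013	117	5.32
year	2014	125	5.68
year	2015	268	12.18
year	2016	187	8.50
year	2017	219	9.95
year	2018	167	7.59
year	2019	215	9.77
year	2020	293	13.32
year	2021	212	9.64
year	2022	225	10.23
year	2023	172	7.82
sex	Female	1000	45.45
sex	Male	918	41.73
sex	Unknown	282	12.82
age	<18	295	13.41
age	18-45	251	11.41
age	45-65	599	27.23
age	65-75	341	15.50
age	>=75	192	8.73
age	Unknown	522	23.73
reporter	Physician	1372	62.36
reporter	Pharmacist	392	17.82
reporter	Other health professional	319	14.50
reporter	Consumer	114	5.18
reporter	Unknown	3	0.14
country	United States	698	31.73
country	Unknown	639	29.05
country	France	250	11.36
country	Germany	148	6.73
country	United Kingdom	128	5.82
country	Italy	122	5.55
country	Australia	114	5.18
country	Canada	101	4.59
route	Oral	1520	69.09
route	Other	680	30.91
outcome	Other serious	1277	45.79
outcome	Hospitalization	1043	37.40
outcome	Death	328	11.76
outcome	Life-threatening	98	3.51
outcome	Disability	39	1.40
outcome	Required intervention to prevent permanent impairment/damage	3	0.11
outcome	Congenital anomaly	1	0.04
onset	<7	95	5.98
onset	7-28	353	22.22
onset	28-60	312	19.63
onset	>=60	605	38.07
onset	Unknown	224	14.10
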