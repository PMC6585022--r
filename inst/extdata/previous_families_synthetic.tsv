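# Families from the earlier Hsa 1/2/8/20 survey that re-enter the congruence
# analysis here.  Only the four family names used in the schematic-topology
# comparison are carried; member rows are representative reconstructions from
# public genome annotation (gene symbol + cytoband), not a transcription of
# the earlier study's member table.  Accessions intentionally absent.
family	family_full	gene	cytoband	accession	source_study
EYA	Eyes Absent Homolog	EYA3	1p36.13	NA	previous
EYA	Eyes Absent Homolog	EYA4	6q23.2	NA	previous
EYA	Eyes Absent Homolog	EYA1	8q13.3	NA	previous
EYA	Eyes Absent Homolog	EYA2	20q13.12	NA	previous
MATN	Matrilin	MATN1	1p35.2	NA	previous
MATN	Matrilin	MATN3	2p24.1	NA	previous
MATN	Matrilin	MATN2	8q22.1	NA	previous
MATN	Matrilin	MATN4	20q13.12	NA	previous
HCK	HCK/SRC-related Tyrosine Kinase	LCK	1p35.2	NA	previous
HCK	HCK/SRC-related Tyrosine Kinase	LYN	8q12.1	NA	previous
HCK	HCK/SRC-related Tyrosine Kinase	BLK	8p23.1	NA	previous
HCK	HCK/SRC-related Tyrosine Kinase	HCK	20q11.21	NA	previous
KCNS	Potassium Voltage-Gated Channel Modifier subfamily S	KCNS3	2p24.2	NA	previous
KCNS	Potassium Voltage-Gated Channel Modifier subfamily S	KCNS2	8q22.2	NA	previous
KCNS	Potassium Voltage-Gated Channel Modifier subfamily S	KCNS1	20q13.12	NA	previous
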