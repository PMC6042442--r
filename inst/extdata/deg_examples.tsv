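gene_symbol	description	log2fc	fdr
PLA2G3	Group 3 secretory phospholipase A2	-3.02	2.88E-02
SLC27A6	solute carrier family 27 (fatty acid transporter) member 6	-1.47	7.5E-03
HOGA1	4-hydroxy-2-oxoglutarate aldolase, mitochondrial	-1.23	3.6E-03
DAPK1	Death-associated protein kinase beta	-1.20	0
NFKBIZ	NF-kappa-B inhibitor zeta	-1.04	1E-05
TM7SF2	Transmembrane 7 superfamily member 2	-0.95	9.9E-03
DHCR7	7-dehydrocholesterol reductase	-0.82	5.18E-11
LSS	lanosterol synthase	-0.66	1.59E-05
DRAM1	DNA damage-regulated autophagy modulator protein 1	-0.60	4.44E-02
SRD5A3	Polyprenol reductase	0.75	2.75E-04
AKR1C4	Aldo-keto reductase family 1 member C4	1.00	6.59E-07
HMOX1	Heme oxygenase 1	1.21	3.12E-03
PDK4	Pyruvate dehydrogenase kinase, isoenzyme 4	2.54	0
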