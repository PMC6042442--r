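term_id	term_name	total_n	significant_nf	fisher_p	genes
GO:0008202	steroid metabolic process	122	15	6.79E-12	INSIG1;DHCR7;AKR1C4;SRD5A3;PCSK9;MVD;APOA1;LDLR;MVK;HSD3B2;HSD11B1;STAR;TM7SF2;LSS;SULT1A3
GO:0006695	cholesterol biosynthetic process	34	7	1.08E-07	INSIG1;DHCR7;MVD;APOA1;MVK;TM7SF2;LSS
GO:0008203	cholesterol metabolic process	89	9	4.28E-07	INSIG1;DHCR7;PCSK9;MVD;APOA1;LDLR;MVK;STAR;TM7SF2
GO:0006694	steroid biosynthetic process	60	7	3.35E-06	DHCR7;MVD;MVK;HSD3B2;STAR;TM7SF2;LSS
GO:0044281	small molecule metabolic process	1410	34	4.28E-06	ANGPTL4;PIK3C2B;ABCB1;INSIG1;FHL2;KYNU;ALDH1A1;DHCR7;HMOX1;HBA2;HBA1;PLA2G3;GPAT3;ACSS2;AKR1C4;HBB;SRD5A3;GLUL;SLC25A20;MVD;PDK4;APOA1;G0S2;LDLR;MVK;HSD3B2;GCLC;BGN;SLC2A3;HSD11B1;STAR;TM7SF2;LSS;SULT1A3
GO:0016126	sterol biosynthetic process	29	5	1.55E-05	INSIG1;DHCR7;MVD;MVK;TM7SF2
GO:0006629	lipid metabolic process	490	16	3.91E-05	INSIG1;DHCR7;FA2H;PLA2G3;AGPAT9;SRD5A3;PCSK9;MVD;APOA1;LDLR;SLC27A6;MVK;HSD11B1;TM7SF2;LSS;SULT1A3
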