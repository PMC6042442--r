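sample_id	raw_reads_million	unmapped_reads_million	mapped_reads_million	mapped_ratio_pct	uniquely_mapped_ratio_pct
Control-1	15.20	1.94	13.26	87.2	83.5
Control-2	15.25	2.09	13.16	86.3	82.7
Control-3	15.15	1.93	13.23	87.3	83.5
CLs-1	19.16	3.18	15.98	83.4	79.2
CLs-2	15.11	1.98	13.13	86.9	83.0
CLs-3	14.72	1.87	12.85	87.3	83.5
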