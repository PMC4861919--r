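chr2	0	50000000	p25.3	gneg
chr2	50000000	93000000	p11.2	gpos50
chr2	93000000	160000000	q21	gneg
chr2	160000000	243000000	q37	gpos50
chr6	0	30000000	p22	gneg
chr6	30000000	61000000	p11	gpos50
chr6	61000000	120000000	q16	gneg
chr6	120000000	171000000	q27	gpos50
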