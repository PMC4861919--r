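gene	chromosome	strand	exon_number	start	end
ESR1	6	+	1	152011001	152012000
ESR1	6	+	2	152101001	152101200
ESR1	6	+	3	152163001	152163300
ESR1	6	+	4	152201001	152201350
ESR1	6	+	5	152265001	152265140
ESR1	6	+	6	152311001	152311140
ESR1	6	+	7	152341001	152341190
ESR1	6	+	8	152411001	152415000
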