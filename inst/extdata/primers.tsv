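name	seq	direction	mutagenic	mutated_positions
LepF1	ATTCAACCAATCATAAAGATATTGG	forward	false	
LepR1	TAAACTTCTGGATGTCCAAAAAATCA	reverse	false	
AmCarp-f_outer	GAATATGAGCCGGAATAGTAGGA	forward	false	
AmCar-r_outer	ATGTGTTGAAGTTACGGTCA	reverse	false	
CYTB-f	TATGTACTACCATGAGGACAAATATC	forward	false	
CYTB-r	ATTACACCTCCTAATTTATTAGGAAT	reverse	false	
AmCar-f	ATTTCMTCAATTATAGGATCATTAAAYTTACC	forward	true	32
AmCar-r	CAGCTAATACAGGTAATGA	reverse	false	
AmCarp-f	AGATATTGGGATCTTGTA	forward	false	
AmCarp-r	CTAGTAACAATTGTATTATAAATTTGATCAGCG	reverse	true	33
AmEu1-f	GGATGAACAGTATATCCACC	forward	false	
AmEu1-r	GTAACTATTAAGTTTAATGATCCTATAATAGC	reverse	true	32
AmEu2-f	CTTTAATACTAGGATCACCTGATATAGCGAT	forward	true	31
AmEu2-r	CTGATAATGGTGGATATA	reverse	false	
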