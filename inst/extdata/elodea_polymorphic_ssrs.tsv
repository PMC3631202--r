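context	motif	unit	usa_count	fin_count	start	end
intron	A	1	9	10	9629	9638
IGS	T	1	9	7	13777	13785
IGS	T	1	6	7	14114	14120
gene	T	1	4	7	23797	23803
IGS	A	1	10	9	27738	27747
IGS	T	1	12	11	28231	28242
IGS	A	1	6	7	32825	32831
IGS	T	1	8	9	33664	33672
IGS	C	1	4	5	38106	38110
intron	T	1	9	8	44532	44540
IGS	AT	2	7	6	47164	47177
IGS	T	1	13	9	47854	47866
IGS	T	1	10	9	49242	49251
IGS	T	1	8	10	53899	53903
IGS	T	1	9	16	56245	56260
IGS	T	1	8	6	56368	56375
IGS	T	1	7	6	62082	62088
IGS	T	1	7	4	64758	64764
IGS	T	1	11	12	65835	65846
IGS	T	1	6	7	67023	67029
IGS	T	1	10	8	70048	70057
IGS	TA	2	5	6	70071	70082
IGS	T	1	8	7	75626	75633
intron	G	1	7	8	77248	77255
IGS	T	1	8	11	79490	79500
IGS	A	1	7	8	82761	82768
intron	TA	2	9	6	83499	83516
IGS	T	1	9	10	86262	86271
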