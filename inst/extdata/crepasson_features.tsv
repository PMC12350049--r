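gene	start	end	strand	size	anticodon	start_codon	stop_codon
tRNA-Phe	1	69	H	69	GAA		
12S rRNA	70	1022	H	953			
tRNA-Val	1023	1094	H	72	TAC		
16S rRNA	1095	2775	H	1681			
tRNA-Leu(L2)	2776	2851	H	76	TAA		
ND1	2852	3826	H	975		ATG	TAA
tRNA-Ile	3831	3902	H	72	GAT		
tRNA-Gln	3901	3971	L	71	TTG		
tRNA-Met	3973	4041	H	69	CAT		
ND2	4042	5086	H	1045		ATG	T--
tRNA-Trp	5087	5157	H	71	TCA		
tRNA-Ala	5160	5228	L	69	TGC		
tRNA-Asn	5230	5302	L	73	GTT		
tRNA-Cys	5336	5402	L	67	GCA		
tRNA-Tyr	5402	5472	L	71	GTA		
COI	5474	7021	H	1548		GTG	TAA
tRNA-Ser(S2)	7021	7092	L	72	TGA		
tRNA-Asp	7096	7167	H	72	GTC		
COII	7182	7872	H	691		ATG	T--
tRNA-Lys	7873	7948	H	76	TTT		
ATP8	7950	8114	H	165		ATG	TAG
ATP6	8108	8790	H	683		ATG	TA-
COIII	8791	9575	H	785		ATG	TA-
tRNA-Gly	9576	9648	H	73	TCC		
ND3	9649	9997	H	349		ATG	T--
tRNA-Arg	9998	10067	H	70	TCG		
ND4L	10068	10364	H	297		ATG	TAA
ND4	10358	11738	H	1381		ATG	T--
tRNA-His	11739	11807	H	69	GTG		
tRNA-Ser(S1)	11808	11877	H	70	GCT		
tRNA-Leu(L1)	11879	11951	H	73	TAG		
ND5	11955	13778	H	1824		ATG	TAA
ND6	13775	14296	L	522		ATG	TTA
tRNA-Glu	14297	14365	L	69	TTC		
Cytb	14371	15511	H	1141		ATG	TT-
tRNA-Thr	15512	15583	H	72	TGT		
tRNA-Pro	15583	15653	L	71	TGG		
CR	15654	16571	H	918			
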