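chrom	arm	start	end
chr1	1p	0	121535434
chr1	1q	124535434	249250621
chr2	2p	0	92326171
chr2	2q	95326171	243199373
chr3	3p	0	90504854
chr3	3q	93504854	198022430
chr4	4p	0	49660117
chr4	4q	52660117	191154276
chr5	5p	0	46405641
chr5	5q	49405641	180915260
chr6	6p	0	58830166
chr6	6q	61830166	171115067
chr7	7p	0	58054331
chr7	7q	61054331	159138663
chr8	8p	0	43838887
chr8	8q	46838887	146364022
chr9	9p	0	47367679
chr9	9q	50367679	141213431
chr10	10p	0	39254935
chr10	10q	42254935	135534747
chr11	11p	0	51644205
chr11	11q	54644205	135006516
chr12	12p	0	34856694
chr12	12q	37856694	133851895
chr13	13p	0	16000000
chr13	13q	19000000	115169878
chr14	14p	0	16000000
chr14	14q	19000000	107349540
chr15	15p	0	17000000
chr15	15q	20000000	102531392
chr16	16p	0	35335801
chr16	16q	38335801	90354753
chr17	17p	0	22263006
chr17	17q	25263006	81195210
chr18	18p	0	15460898
chr18	18q	18460898	78077248
chr19	19p	0	24681782
chr19	19q	27681782	59128983
chr20	20p	0	26369569
chr20	20q	29369569	63025520
chr21	21p	0	11288129
chr21	21q	14288129	48129895
chr22	22p	0	13000000
chr22	22q	16000000	51304566
chrX	Xp	0	58632012
chrX	Xq	61632012	155270560
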