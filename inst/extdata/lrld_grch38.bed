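chr1	47761740	51761740
chr1	125169943	125170022
chr2	85919365	100517106
chr2	134242429	138242430
chr2	182135273	189135274
chr3	47483505	49987563
chr3	83368158	86868160
chr5	44464140	50455870
chr5	128972101	131972101
chr6	25391792	33424245
chr6	57788603	58453888
chr6	139637169	142137170
chr7	54964812	66897578
chr8	8105067	12105082
chr8	43025699	48924888
chr8	110918594	113918595
chr10	36671065	43184546
chr11	87860352	90860352
chr12	33108733	41713733
chr20	32536339	35066586
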