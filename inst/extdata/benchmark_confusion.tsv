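tool	TP	FP	TN	FN	accuracy	sensitivity	specificity	precision	f1
Xlnc1DCNN	20895	1204	14087	821	94.53	96.22	92.13	94.55	95.38
CPC2	21023	6457	8834	693	80.68	96.81	57.77	76.50	85.47
CNIT	21307	3580	11711	409	89.22	98.12	76.59	85.61	91.44
PLEK	20704	6665	8626	1012	79.26	95.34	56.41	75.65	84.36
CPAT	20646	2597	12694	1070	90.09	95.07	83.02	88.83	91.84
FEELnc	20023	1182	14109	1693	92.23	92.20	92.27	94.43	93.30
RNAsamba	20998	1795	13496	718	93.21	96.69	88.26	92.12	94.35
lncRNA_Mdeep	20813	1799	13492	903	92.70	95.84	88.23	92.04	93.90
LncADeep	20232	1113	14178	1484	92.98	93.17	92.72	94.79	93.97
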