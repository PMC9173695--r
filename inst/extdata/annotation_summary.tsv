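category	amount	with_entries	with_entries_pct	without_entries	without_entries_pct
TP	20895	1692	8.10	19203	91.90
TN	14087	13085	92.89	1002	7.11
FP	1204	704	58.47	500	41.53
FN	821	463	56.39	358	43.61
all_missed_FP	344	93	27.03	251	72.97
all_missed_FN	105	90	85.71	15	14.29
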