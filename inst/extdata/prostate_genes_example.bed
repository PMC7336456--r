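# Example prostate-cancer gene intervals (hg19, approximate spans).
# For demonstrating annotate_genes(); supply your own curated BED for
# real analyses.
chr1	223889000	223964000	CAPN2
chr2	47630206	47710367	MSH2
chr2	48010221	48034092	MSH6
chr3	37034841	37107338	MLH1
chr3	170780000	171178000	TNIK
chr5	67584251	67597649	PIK3R1
chr5	112043195	112181936	APC
chr8	71060000	71316000	NCOA2
chr8	128747680	128753674	MYC
chr10	89622870	89731687	PTEN
chr11	69455873	69469242	CCND1
chr11	108093211	108239829	ATM
chr12	25358180	25403854	KRAS
chr13	32889611	32973805	BRCA2
chr13	48877883	49056026	RB1
chr14	38058757	38064325	FOXA1
chr17	7565097	7590856	TP53
chr17	47676246	47755525	SPOP
chr20	57414773	57486247	GNAS
chrX	66763874	66950461	AR
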