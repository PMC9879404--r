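# Pathogenic STR locus catalog (hg19, 1-based positions).
# Pathogenic lengths (bp) are published disease thresholds; coordinates are
# approximate literature values for the repeat start; ref_bp is a typical
# normal-range allele length used as the reference allele.
gene	chrom	pos	unit	ref_bp	pathogenic_bp
AR	chrX	66765159	GCA	66	114
TCF4	chr18	53253385	CTG	45	150
DMPK	chr19	46273463	CTG	36	150
DIP2B	chr12	50898785	GGC	21	600
ATXN10	chr22	46191235	ATTCT	70	4000
RFC1	chr4	39350045	AAAAG	55	4000
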