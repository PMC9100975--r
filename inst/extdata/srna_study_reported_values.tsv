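metric	value
raw_reads_total	67371464
high_n_reads	275357
five_prime_adapter_reads	106181
no_three_prime_adapter_reads	1155625
poly_nt_reads	55266
clean_reads_total	65779035
read_length_nt	50
gigabases_reported	3.37
q20_percent_mean	98.73
q30_percent_mean	95.63
gc_percent_mean	50.65
inrange_18_30_total	52233007
inrange_18_30_xylem	23684340
inrange_18_30_phloem	28548667
mirna_total	134
mirna_known	132
mirna_novel	2
de_total	58
de_up	21
de_down	37
de_percent_reported	43.28
mir171_xylem_rptm	1064.13
mir171_phloem_rptm	50.09
mir171_fold_reported	20
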