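sample	raw_reads	clean_reads	q30_percent	gc_percent	mapped_rate_percent
P1	11419418	11161174	95.96	50.74	90.07
P2	11768425	11432450	95.47	51.42	95.10
P3	11997478	11760792	95.83	50.77	91.37
X1	10320359	10100623	95.85	50.13	97.40
X2	10796007	10499531	95.17	50.58	97.22
X3	11069777	10824465	95.52	50.27	97.39
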