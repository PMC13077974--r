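category	pct_annotator1	pct_annotator2	kappa
GENE	18.6	18.3	0.85
CDNA_PROT	14.2	14.0	0.81
DISEASE	16.8	16.5	0.82
SIGNIFICANCE	9.3	9.5	0.77
ZYGOSITY	7.1	7.0	0.74
INHERITANCE_MODE	6.5	6.4	0.76
PHENOTYPE	5.9	6.0	0.75
OMIM_CLINVAR_ID	8.4	8.6	0.79
RECOMMENDATION	5.2	5.1	0.73
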