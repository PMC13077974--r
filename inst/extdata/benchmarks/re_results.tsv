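relation	RuBERT	RuBioBERT	ModernBERT
variant_in_gene	0.82	0.86	0.91
gene_associated_with	0.75	0.80	0.88
variant_significance	0.72	0.78	0.85
disease_inheritance	0.70	0.75	0.82
phenotype_supports_disease	0.66	0.71	0.79
variant_linked_to_omim	0.73	0.79	0.84
retest_recommended_for	0.62	0.68	0.76
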