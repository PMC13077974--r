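model	precision	recall
RuBERT	0.84	0.80
RuBioBERT	0.87	0.83
ModernBERT	0.90	0.87
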