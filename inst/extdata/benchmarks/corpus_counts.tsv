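group	reports	total_entities
authentic	318	2860
synthetic	5000	45140
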