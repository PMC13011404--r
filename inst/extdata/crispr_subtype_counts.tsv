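system_type	subtype	count
I	I-C	57
I	I-E	41
I	I-G	80
II	II-A	86
II	II-C	12
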