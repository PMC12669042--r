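entity_id	category
M0001	a
M0002	d
M0003	d
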