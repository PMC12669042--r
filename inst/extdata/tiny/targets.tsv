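entity_id	entity_name	protein_id
M0001	molecule_M0001	P0001
M0001	molecule_M0001	P0003
M0002	molecule_M0002	P0006
M0002	molecule_M0002	P0007
M0003	molecule_M0003	P0002
M0003	molecule_M0003	P0005
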