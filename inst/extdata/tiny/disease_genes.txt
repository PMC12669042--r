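P0001
P0003
P0004
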