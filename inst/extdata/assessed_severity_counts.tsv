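severity	n
none	181
mild	27
moderate	24
severe	18
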