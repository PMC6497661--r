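{"seed":101,"shifts":[{"edge":4,"delta":[2.44948974278318,2.44948974278318]}]}
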