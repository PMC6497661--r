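{"curves":[{"ids":[0,1,2,3],"fixed_ends":true}],"pairs":[[4,8],[5,9],[6,10],[7,11]],"midline":[0,1,2,3]}
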