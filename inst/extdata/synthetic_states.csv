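"species","diet"
"sp_0001","insectivore"
"sp_0002","frugivore"
"sp_0003","insectivore"
"sp_0004","frugivore"
"sp_0005","frugivore"
"sp_0006","frugivore"
"sp_0007","insectivore"
"sp_0008","frugivore"
"sp_0009","insectivore"
"sp_0010","frugivore"
"sp_0011","insectivore"
"sp_0012","frugivore"
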