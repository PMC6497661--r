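(((sp_0011:0.3272952641,sp_0008:0.3272952641):0.65282761,(sp_0003:0.1205899952,(sp_0009:0.05253105202,sp_0007:0.05253105202):0.0680589432):0.8595328789):0.01987712592,(sp_0001:0.7542412081,((((sp_0002:0.2043272816,sp_0005:0.2043272816):0.2182660168,(sp_0012:0.09584608465,sp_0006:0.09584608465):0.3267472138):0.07379638127,sp_0004:0.4963896797):0.2176522558,sp_0010:0.7140419355):0.04019927261):0.2457587919);
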