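id position a0 a1
snp0001 11000 A G
causal1 12000 A G
snp0003 13000 A G
snp0004 14000 A G
snp0005 15000 A G
snp0006 16000 A G
snp0007 17000 A G
snp0008 18000 A G
snp0009 19000 A G
snp0010 20000 A G
snp0011 21000 A G
snp0012 22000 A G
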