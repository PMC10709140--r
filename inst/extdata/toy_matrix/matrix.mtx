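%%MatrixMarket matrix coordinate integer general
3 2 3
1 1 5
2 2 7
3 1 2
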