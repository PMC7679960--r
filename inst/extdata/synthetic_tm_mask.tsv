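# synthetic transmembrane-segment mask (1-based, inclusive)
6	28
35	55
62	84
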