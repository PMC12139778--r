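{"spots_green":42,"spots_farred":25,"pairs":22,"orphaned":0,"retained":21,"rejected":1}
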