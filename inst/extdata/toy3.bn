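# Three-gene toy model: a single 5-cycle attractor under synchronous update
targets, factors
A, C
B, A & C
C, !B
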