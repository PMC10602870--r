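>flank40_right_synthetic
GGCCTCAAGAGGCGACTAACCGTTCCGGTCTGATCGTGGT
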