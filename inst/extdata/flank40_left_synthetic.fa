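>flank40_left_synthetic
CCAGTATCCTACCTATCTTAGTGCCAGGTTGTCCGAACTA
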