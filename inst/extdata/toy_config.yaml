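# Toy end-to-end pipeline configuration: a 21-bp synthetic core with 60-bp
# flanks (so both cleavage sites, dyad +/- 53 nt, stay on the construct) and
# 12 variants with planted dyad distributions built from peaks at the
# canonical position and ~one helical turn to either side.
name: toy_21bp
seed: 42
construct:
  core_seq: GGCGATCAGCTGACTGCAGGC
  left_flank: CAAAAATCTTCGTCTGCTCATAAGAGGGCTGGGCGCGGATAAATGTGTTCGATGTAACCT
  right_flank: GCTCAGCAATGCTGGAGCGGCACGGACCACATGCATTGTTAGAGCAACAGGCCAAGTTCA
reference_peaks: [0]
reference_weights: [1.0]
depth: 300
error_rate: 0.0
read_length: 150
max_mismatches: 2
bg_quantile: 0.10
combine: regression
nmf_rank: 3
cluster_k: 3
variants:
  - {label: "A_4[-6:-3]",  peaks: [0],        weights: [1.0]}
  - {label: "A_4[1:4]",    peaks: [0],        weights: [1.0]}
  - {label: "A_5[-8:-4]",  peaks: [-11],      weights: [1.0]}
  - {label: "A_6[-3:2]",   peaks: [-11],      weights: [1.0]}
  - {label: "M_2[-2:-1]",  strand: top,    peaks: [0, -11],  weights: [0.5, 0.5]}
  - {label: "M_3[0:2]",    strand: top,    peaks: [0, -11],  weights: [0.5, 0.5]}
  - {label: "M_2[-2:-1]",  strand: bottom, peaks: [0],       weights: [1.0]}
  - {label: "M_1[3:3]",    strand: top,    peaks: [0],       weights: [1.0]}
  - {label: "I_1[-1^0]",   strand: top,    peaks: [11],      weights: [1.0]}
  - {label: "I_1[-1^0]",   strand: bottom, peaks: [11],      weights: [1.0]}
  - {label: "I_1[2^3]",    strand: top,    peaks: [0, 11],   weights: [0.7, 0.3]}
  - {label: "I_1[4^5]",    strand: bottom, peaks: [0],       weights: [1.0]}
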