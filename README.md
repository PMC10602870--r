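# nucleoslide

Nucleosome repositioning analysis from site-specific cleavage sequencing,
with a kinetic model of remodeler-driven sliding.

Chromatin remodelers like Chd1 bind nucleosomes at the symmetric SHL±2
sites and pump DNA toward the dyad, sliding the histone core in 1-bp
steps. Local DNA perturbations — poly(dA:dT) tracts, mismatches,
single-nucleotide insertions — raise the cost of the +1 nt twist-defect
intermediate the remodeler needs, biasing which side slides. This package
is for people studying that interplay *in silico*: it builds the
perturbation libraries, simulates the cleavage-sequencing readout with
known ground truth, calls dyad distributions from the reads, runs the
positioning-pattern analytics, and solves the sliding kinetic model.

## What is implemented

**Library design** — a core positioning sequence (145-bp 601-derived
default) with flanks (40N40), dyad-relative coordinates and SHL
conversion, and builders for the three libraries with the field's label
notation `A_L[a:b]`, `M_n[a:b]`, `I_1[a^b]` (1781 tract variants on the
145-bp core for lengths 3–15).

**Read simulation** — each nucleosome event cleaves both strands 53 nt 5′
of the dyad; one read per strand starts at the cleavage site and runs 3′
(150-nt cap, optional substitution errors, truth kept in read ids, FASTQ
in/out via Biostrings).

**Dyad calling** — variant-aware exhaustive matching (fewest Hamming
mismatches, variation-certified ties preferred, reference collapse for
variation-less reads), the discard rule *variation and cleavage must be
identified*, per-strand cleavage profiles, uniform background
subtraction, the positioning signal `top[d−53] + bottom[d+53]` and its
least-squares strand-combination variant, normalized to probabilities.

**Pattern analytics** — Lee–Seung NMF into basis dyad patterns with
geographic (length × position) score maps, `exp(−JSD)` similarity with
normalized-Laplacian spectral clustering and silhouettes, and
KL-divergence maps against the unperturbed positioning.

**Defect energetics** — the defect coordinate `d2 = s15 − s25 + 1` nt,
the tail-odds cost estimator `ΔF = −log P(d2 > 0.5) + log P(d2 < 0.5)`
(kBT, binomial SE), Gaussian fits of cost versus tract location, and the
width law `σ(L)` by linear regression.

**Kinetic model** — master equation over 225 positions with the
sinusoidal landscape `F(i) = −(A/2)cos(2π(i−i0)/Δ)` (A = 10 kBT,
Δ = 10.5 bp), Gaussian defect costs at SHL∓2 (height 2 kBT, centres ∓21
bp, width `0.22·L + 1.1` bp), ATP-driven rates, closed-form steady state
cross-checked by exact time evolution, effective free energy
`F_eff = −log p_eq`, and the barrier metrics
`ΔF10 = F_eff(−10) − F_eff(0)`, `ΔF1 = F_eff(−1) − F_eff(0)` with
location × length heatmaps.

## Worked example

The numbered drivers under `analysis/` run the whole workflow on the
bundled toy configuration (21-bp core, 60-bp flanks, 12 variants with
planted dyad distributions) and write TSV tables under `results/`:

```sh
Rscript analysis/02_simulate_reads.R
Rscript analysis/03_call_dyads.R
Rscript analysis/04_pattern_analysis.R
```

prints, among other things:

```
simulated 7200 reads for 12 variants (0 events dropped)
top strand: cleavage = 1.0000 * dyad -53.0000 (expect slope 1, offset -53)
bottom strand: cleavage = 1.0000 * dyad +53.0000 (expect slope 1, offset +53)
NMF rank 3: 500 iterations, final error 0.0008386
  basis 1 peaks at construct position 81 (dyad-relative +11)
  basis 2 peaks at construct position 70 (dyad-relative +0)
  basis 3 peaks at construct position 59 (dyad-relative -11)
```

The detected cleavage sites regress onto the planted dyads with exactly
the ±53 nt offsets of the two crosslink sites, and NMF recovers the three
planted dyad patterns (canonical, and ±1 helical turn). Two thirds of
reads certify their variant; the remainder are reads whose perturbation
lies on the unsequenced strand, collapsed into the reference pool exactly
as the one-cleavage-one-strand rule prescribes (`qc.tsv`).

The energetics and kinetics drivers:

```sh
Rscript analysis/05_defect_energetics.R
Rscript analysis/06_kinetic_model.R
```

```
sigma(L) = 0.222 * L + 1.085 bp (planted law: 0.22 L + 1.1)
no tract: dF10 = 0.222 kBT, dF1 = 0.869 kBT
10-bp tract at x = -30: dF10 = 9.462 kBT, dF1 = 0.917 kBT
evolution vs closed form, L1 distance: 3.72e-15
```

The tail-odds estimator plus Gaussian fitting recovers the planted defect
width law from simulated defect-coordinate series, and a 10-bp tract
starting at SHL−3 raises the overall barrier for the favoured −10 bp
shift from 0.22 to 9.5 kBT while barely touching the initial barrier —
the signature of barrier extension by strong positioning phasing.

```r
library(nucleoslide)
el <- effective_landscape(model = defect_cost_model(tract_length = 10, tract_x = -30))
barrier_metrics(el)
#>      dF10       dF1
#> 9.4621243 0.9173222
```

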