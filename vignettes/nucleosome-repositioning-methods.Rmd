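---
title: "Methods: dyad calling from site-specific cleavage and the sliding kinetic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyad calling from site-specific cleavage and the sliding kinetic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoslide)
```

## The scientific problem

Chromatin remodelers such as Chd1 engage nucleosomal DNA at the two
symmetric SHL±2 sites and pump DNA toward the dyad, sliding the histone
core in 1-bp steps. Local DNA perturbations — poly(dA:dT) tracts,
mismatched base pairs, single-nucleotide bulges — change how easily the
remodeler forms its +1 nt twist-defect intermediate, and therefore where
nucleosomes end up after rounds of back-and-forth sliding. `nucleoslide`
implements the computational side of that study: perturbation library
design, simulation of the site-specific cleavage sequencing readout, dyad
calling, positioning-pattern analytics, twist-defect energetics
estimators, and a driven master-equation model whose steady state explains
why perturbations accumulate about one helical turn *outside* the
remodeler binding site (around SHL3).

## Constructs, coordinates, libraries

A construct is a core positioning sequence (145 bp for the 601-derived
default) flanked by linker DNA (40 bp each side; "40N40", 225 bp total).
The dyad sits at the core centre (construct index 112 for the default);
dyad-relative coordinates are signed bp with negative values on the
TA-poor side, and continuous super-helix locations are `bp / 10.45`.
Variant labels use the inclusive dyad-relative notation `A_L[a:b]`
(duplex poly(dA:dT) tract), `M_n[a:b]` (window of n consecutive positions
with every non-A:T pair replaced by A on the top or T on the bottom
strand — one variant per strand per window), and `I_1[a^b]` (single A
inserted between adjacent positions on one strand). The builders
enumerate every placement that fits in the core; for the 145-bp core and
tract lengths 3–15 that is `sum(146 - (3:15))` = 1781 tract variants.
The mismatch notation carries no strand, so the package keys records
internally on `label` plus a strand suffix.

Two points are design choices rather than given facts. First, the dyad is
placed at the core centre; the exact dyad register of the 601 145-mer is a
convention, and the centre is the standard one. Second, the shipped FASTA
assets are editable conveniences: the 147-bp Widom 601 is the widely
published sequence (the central 145 bp are used as the core), while the
flanks and the SWH1 +1 record are synthetic stand-ins (generated, labelled
`*_synthetic`), because the study-specific sequences are not bundled.
Every test builds its own toy constructs in code, so no result depends on
an asset.

## The simulated sequencing readout

Each nucleosome event cleaves both DNA backbones 53 nt 5′ of the dyad —
one site per strand — and only sequence 3′ of the cleavage is recovered.
The generator therefore emits, per event, one top-strand read starting at
construct index `dyad − 53` running rightward and one bottom-strand read
whose 5′ end maps to `dyad + 53` (emitted as the reverse complement of the
covered top-strand segment), both capped at the 150-nt read length of a
150×150 paired-end run. This deliberately collapses the paired-end
protocol to "sequence from the cleavage site 3′-ward": adapter content,
mates, PCR duplicates and quality-score variation carry no information the
caller uses, so they are not modelled; qualities are constant and the
error model is substitution-only (default rate 0.001, default depth 2000
events per variant, everything seeded). Ground truth (variant, planted
dyad, cleavage site) rides in the read id, which is what makes every
downstream stage testable end to end.

What the generator does *not* emulate about real libraries: leak-through
of uncleaved molecules past the streptavidin depletion, indel sequencing
errors, PCR bias between variants, and day-to-day depth variation. Tests
passing on synthetic data certify the algebra of the pipeline (coordinate
maps, filtering rules, signal definitions), not robustness to those
artifacts; the background-subtraction and mismatch-tolerance knobs exist
for them but are exercised here only on synthetic noise.

## Dyad calling

Reads are matched against every variant strand (and the canonical
reference strands) at all offsets by Hamming distance — the references are
≤ 226 nt and the library enumerable, so a bespoke matcher is fully
specified where a general aligner would add configuration surface. Best
candidate wins by fewest mismatches, ties broken in favour of candidates
whose perturbed window overlaps the read, because such a read *certifies*
its variant. A read consistent only with canonical sequence (perturbation
5′ of the cleavage) is indistinguishable between variants by construction;
the default "reference collapse" mode keeps it in a reference pool with
its cleavage site (the one-cleavage-one-strand rule), and a strict mode
discards it as ambiguous. Insertion variants shift coordinates by one on
the perturbed strand 3′ of the bulge, so cleavage positions are mapped
back through the variant's gap map; the inserted base itself maps to the
next reference base 3′ of it, keeping "first retained reference position"
semantics.

Filtering mirrors the discard rule *variation and cleavage must both be
identified*; the QC tally reports category counts and the kept fraction.
Per-variant, per-strand cleavage counts are floored by a uniform
subtraction of a per-profile quantile (default 0.10 — the level is a
choice; the rule itself is just "subtract a flat floor and clip at
zero"). The positioning signal at dyad candidate `d` is defined as
`top[d − 53] + bottom[d + 53]`; the default combination instead solves the
small least-squares problem `top[d−53] ≈ a_t·s[d]`, `bottom[d+53] ≈
a_b·s[d]` (best rank-1 approximation of the 2×T shifted-profile matrix,
normalized so `a_t + a_b = 2`), which reduces to the plain sum when the
strands agree and to the shifted single profile when one strand is empty.
The exact regression the original analysis used is not specified beyond
"a linear regression model combining both strands"; this contract is one
consistent reading and the plain sum is kept as the documented
alternative. Signals are normalized to per-variant probability vectors.

## Pattern analytics

The variants × positions probability matrix is decomposed by NMF using
Lee–Seung multiplicative updates on squared Frobenius error, with seeded
random nonnegative initialization (the original initialization is
unstated; a fixed seed makes runs reproducible). Basis rows are
normalized to sum 1 with scale moved into the weights — the scale split in
NMF is arbitrary and affects absolute scores, not patterns. Default ranks
follow the observed pattern counts: 3 before sliding (clean / noisy /
split), 4 after (dyad[−20], dyad[−11], dyad[zero], dyad[+20] or noisy).
Weights are mapped onto the bp covered by each variant's perturbation,
averaging overlaps, to give the geographic (length × position) score maps;
empty cells are `NA`, never zero. Similarity between positioning
distributions is `exp(−JSD)` with the divergence in nats (so disjoint
supports score exactly 0.5), clustered by normalized-Laplacian spectral
embedding plus seeded k-means, with mean silhouette widths reported over
candidate k to support the "minimal number of well-isolated clusters"
choice. Deviation from the unperturbed positioning is `KL(perturbed ‖
original)` with a pseudocount of 1e-6 added to both distributions (nats;
the pseudocount keeps empty positions finite and vanishes from the map at
the reported precision), mapped onto perturbation coordinates the same
way.

## Twist-defect energetics

The defect coordinate is `d2 = s15 − s25 + 1` nt, built from phosphate
progress at SHL1.5 and SHL2.5 (the +1 accounts for the defect already
present in the remodeler-bound reference conformation). The defect cost
is the tail log-odds `ΔF = −log P(d2 > 0.5) + log P(d2 < 0.5)` in kBT,
with samples exactly at the 0.5-nt threshold excluded from both events
and a delta-method binomial standard error `sqrt(1/n_above + 1/n_below)`;
an empty tail is flagged infinite rather than returned as a number.
Cost-versus-location curves are fitted with `A·exp(−(k−μ)²/2σ²)` by
seeded multistart Levenberg–Marquardt, and the width law `σ(L)` by
ordinary least squares (the planted law is `0.22·L + 1.1` bp). Tract
location `k` follows the tract-centre convention; the source analysis
does not state whether `k` indexes tract start or centre, so the choice
is flagged here and used consistently in the kinetic model. The
free-energy histogram utility uses 0.05-nt bins (unstated upstream; fine
enough to resolve the 0.5-nt threshold, coarse enough to be smooth at
10^4 frames).

## The kinetic model

Positions live on the integer grid `i = −N/2 … N/2` with `N + 1 = 225`
(the DNA length; edge placement is immaterial for central tracts, and the
boundaries are reflecting). Three energies, all in kBT:

* the positioning landscape `F(i) = −(A/2)·cos(2π(i − i0)/Δ)`, A = 10,
  Δ = 10.5 bp (= 147/14), i0 = 0;
* the added defect cost at the engaged SHL2: a Gaussian in tract location
  `k = x − i`, height 2 kBT, centred at −21 bp for SHL−2 with width
  `σ(L) = 0.22·L + 1.1` bp; SHL+2 uses the mirror at +21 bp, justified by
  the two-fold symmetry of the nucleosome (only the SHL−2 curve is
  measured). The 2-kBT height strictly holds for tracts longer than ~4
  bp; shorter tracts reuse it (configurable);
* `ΔF_ATP = 20` kBT driving sliding from the engaged SHL2 toward the
  dyad, with overall rate constant `D` (inverse time).

One deliberate sign choice: the driven-rate expressions as printed carry
`exp(−ΔF_ATP/kBT)`, which would make ATP-driven sliding *slower* than
spontaneous back-sliding and contradicts the accompanying dominance
argument (`ΔF_ATP = 20 kBT ≫` everything else). The package applies
`exp(+ΔF_ATP/kBT)` to the two driven rates so driven sliding dominates;
the factor cancels from the steady-state ratio either way, so every
equilibrium quantity is unaffected. Totals use the dominant-term
approximation (driven terms only), which makes the printed ratio law
`p(i+1)/p(i) = exp(−(ΔF_d+2(i) − ΔF_d−2(i+1) + F(i+1) − F(i)))` exact and
recovers detailed balance with the Boltzmann distribution in the ATP-free,
defect-free limit; exact two-term totals are available behind an option
and differ by ~e^−40 at the default parameters.

The steady state is built from cumulative products of that ratio in log
space (no overflow on 225 sites) and cross-checked by exact linear
propagation of the master equation — `expm` of the tridiagonal generator
with time doubling — which conserves probability to machine precision and
agrees with the closed form to L1 < 1e−8. The effective free energy is
`F_eff = −log p_eq`, anchored `F_eff(0) = F(0)` since additive constants
are unobservable, and verified against the increment recursion to 1e−10.
Barrier metrics are plain differences, `ΔF10 = F_eff(−10) − F_eff(0)` and
`ΔF1 = F_eff(−1) − F_eff(0)`; heatmaps evaluate them over a tract
location × length grid (one landscape per cell). Finite-time
distributions are exposed deliberately: whether a 5-minute sliding
endpoint reaches the steady state is an open experimental question, so
`evolve_master_equation()` reports the transient as well.

## Problem sizes, tolerances, tie-breaks

The bundled toy configuration uses a 21-bp core with 60-bp flanks (so
both cleavage sites stay on the construct), 12 sequence-distinct variants
with planted point-mass dyad mixtures at {−11, 0, +11} bp, 300 events per
variant and zero sequencing error; that size makes end-to-end recovery
*exact* (the called signal equals the empirical draw bit-for-bit), which
is the strongest available oracle. Statistical fixtures use n = 1e5
frames for the tail estimator (bias asserted below one binomial SE,
averaged over 20 replicates), 3σ bands for empirical frequencies, and
seeded RNG throughout; k-means uses 25 restarts; NMF convergence is a
relative error change below 1e−8 with eps-guarded denominators.
Degenerate inputs are first-class: zero-sum signals, all-zero dyad
distributions, empty tails, flat Gaussian-fit inputs and rank overflows
all raise or flag rather than return numbers.

## Known limitations

The matcher is exhaustive over the variant library and not a genome
aligner; it is adequate for library-scale references only. Identical
variant sequences (e.g. a tract placement whose flanking base extends the
run, or an insertion adjacent to an identical base) are honestly
ambiguous and left unassigned — real libraries contain such degeneracies.
Coarse-grained MD itself is out of scope: the defect-energetics module
analyses series, it does not generate trajectories. The NMF score maps
and barrier heatmaps are returned as matrices/TSV; rendering onto 3D
nucleosome structures is out of scope.
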