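---
title: "Methods: fixed-backbone sequence design in seqevolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fixed-backbone sequence design in seqevolve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`seqevolve` searches sequence space for amino-acid sequences that score as
stable on a fixed backbone, using statistical potentials of the kind used in
threading and fold recognition. This vignette is the package's account of the
model, its tunable parameters, the numerical and design choices that were
genuinely open, and what the synthetic test fixtures do and do not establish.

## The scoring model

A target is a single chain: per residue a Cα coordinate, a Cβ coordinate (Cα
for glycine), a side-chain centroid, and one of the seven STRIDE states
H, G, I, E, B, T, C. The sequence is the only variable; the backbone never
moves. Six terms are combined:

**Burial.** Each residue's exposure is summarized by the number of other
residues with Cβ within 14 Å, discretized into 7 states whose boundaries are
the equal-frequency quantiles of the counts over the reference set (the
"BURIAL-Cβ-14-7" alphabet). The pseudo-energy is the negative log-odds of
seeing amino acid *a* in state *s* against its overall frequency, with +1
pseudocounts: `E(s,a) = -ln[(N(s,a)+1)/(N(s)·f(a)+1)]`. The pseudocounts
matter: small reference sets must never produce infinities, and the tables
remain exactly reproducible by a brute-force recount (a property the test
suite enforces).

**Secondary-structure preferences.** The same log-odds construction with the
7 STRIDE states in place of burial states. One consequence worth knowing: on
a reference set with a *single* secondary-structure state, observed counts
equal their own expectation and the table is identically zero. The term is
then constant on any target and normalizer calibration refuses it as
degenerate — which is why the package's reference fixtures mix helices and
sheets.

**Contacts.** A distance-dependent pair potential evaluated separately on Cα
atoms and side-chain centroids. Pair distances with sequence separation
|i−j| ≥ 2 are counted in 0.5 Å shells up to 14.5 Å, and converted against the
distance-scaled finite ideal-gas reference state,
`E(a,b,r) = −ln[ N(a,b,r) / ((r/r_ref)^α · N(a,b,r_ref)) ]` with α = 1.61 and
the outermost shell as the reference (energy ≡ 0 there and beyond). Counts are
symmetrized in (a,b) and +1-pseudocounted. The separation cutoff of 2 excludes
i,i+1 pairs, whose geometry is sequence-independent backbone covalency; the
shell width is configurable and 0.5 Å is the conventional order of magnitude.

**Profile.** Analog structures aligned to the target with TM-score ≥ 0.4
(inclusive — an alignment at exactly 0.4000 contributes) vote, per aligned
pair, for the residue *class* of the analog residue at the target position.
Seven physicochemical classes are used instead of 20 amino acids to keep
low-homology profiles from drowning in noise: small polar {G,S,T,C}, large
polar {N,Q}, negative {D,E}, positive {K,R}, hydrophobic {A,V,L,I,M,P},
aromatic {F,W,Y}, and histidine alone (its charge state is too
context-dependent to pool). Rows are normalized with +0.5 per-class
pseudocounts; positions with no contributor fall back to the background class
frequencies, so an empty profile is exactly neutral. The target's own sequence
is *not* added to its profile — including it would bias the engine toward
trivially recovering the native sequence, which is the one thing an
artificially evolved sequence should not need. Profiles computed by external
structure aligners can be imported from the same TSV format.

**Anti-clustering.** Unconstrained optimization of the terms above tends to
fill helices with runs of alanine and strands with blocks of Ile/Val. The
restraint computes, per class, the number of adjacent same-class pairs and
compares it with the fixed-composition permutation null: `E_c = n_c(n_c−1)/L`
and a closed-form variance, giving `z_c`; the penalty is `Σ_c max(0, z_c)`.
Only excess clustering is penalized — dispersion is not an artifact. A
homopolymer scores zero: with the composition fixed, a one-class sequence
cannot exceed its own null. The adjacency window is configurable (±k
neighbours, Monte Carlo null for k > 1); the default k = 1 is the regime the
closed form covers exactly, and the statistic is applied over the whole chain
(a per-segment variant would need segment-level composition nulls that small
segments cannot support).

## Normalization, the 1.0 anchor, and weights

Raw terms live on incomparable scales, so each is z-normalized per target
against `n_random` (default 200) random sequences drawn from the background
composition (bundled UniProtKB/Swiss-Prot release statistics; replaceable).
Orientations are fixed so that native-favouring is positive, and

    fitness = 1 + Σ_t w_t z_t .

Two consequences anchor the scale: random sequences average 1.0 (the
high-temperature plateau of any annealing trajectory), and the fitness is
invariant to adding a constant to any raw term. The per-target calibration
also makes fitness values comparable across targets. A linear
length-independence transform for the raw terms is available
(`fit_length_transform`) and is fitted, not hard-coded — with per-target
z-normalization it is absorbed by the normalizers, but it matters when raw
term values are compared across chain lengths.

Weights default to uniform (1/6). `calibrate_weights` maximizes the mean
native-vs-decoy z-gap, `(f_native − mean(f_decoy))/sd(f_decoy)`, over the
probability simplex by projected coordinate ascent from the uniform start,
with decoys split half-and-half between composition-preserving shuffles and
random background sequences. The objective is deterministic in its inputs and
indifferent to case order; when no direction improves (all terms equivalent),
the uniform start is returned with a warning. Coordinate ascent on a
6-dimensional simplex with a smooth quasi-concave objective is deliberate
low technology: it is reproducible, derivative-free, and the accuracy of the
weights is not a bottleneck of the method.

## The optimizer

Annealing uses the geometric ladder T₀ = 5000, T ← T/1.002, stopping at
0.005, with 2000 Metropolis iterations per level — 6915 levels and
13,830,000 iterations. The `n_tries` control is retained in the schedule
object for fidelity to the GSL-style parameter set but does not multiply the
iteration count; the product interpretation would give ~2.8×10⁹ iterations,
inconsistent with the documented per-run cost of >1.3×10⁷.

Moves are single-point substitutions: position uniform, replacement drawn
from the background composition conditioned on differing from the current
residue (pair-swap moves were considered and left out: they conserve
composition, which is a constraint the profile and burial terms should be
free to break). Acceptance is Metropolis on the fitness difference
(improvements always, deteriorations with probability `exp(Δ/kT)`).

Every stochastic step — start sequence, proposals, acceptance — draws from
one explicit MT19937 stream implemented over `std::mt19937`, whose output
sequence the C++ standard fixes exactly; doubles use the 53-bit construction.
Runs are therefore bit-identical across platforms for a fixed seed, and a
single run per start suffices. The default seed is 5489, the generator's
reference initialisation.

The inner loop evaluates moves incrementally: burial, secondary-structure and
profile deltas are O(1) table lookups, contact deltas touch only the mutated
position's precomputed neighbour list, and the anti-clustering delta updates
only the two affected classes (adjacent-pair counts change only for the old
and new class of the mutated position). The suite enforces agreement between
the incremental and full paths to 1e-9 — the single most important
correctness property of the optimizer — and, on a 10-residue/3-letter toy
problem, that the annealer reaches the optimum found by exhaustive
enumeration of all 3¹⁰ sequences in ≥ 18 of 20 seeds.

## The structural aligner

Profiles need structure alignments. The package ships a TM-align-style
heuristic rather than a port of any specific program (the profile builder
accepts any external aligner's output): seed alignments from gapless
threading at all offsets plus a secondary-structure-identity seed, then
alternating Kabsch superposition and semi-global dynamic programming on the
score matrix `1/(1+(d_ij/d0)²)` with gap penalty −0.6 and free terminal gaps,
iterated until the aligned set is stable (≤ 30 rounds). The final TM-score
(`d0 = 1.24·(L−15)^{1/3} − 1.8`, floored at 0.5, normalized by the target
length) is maximized over superpositions by iterative close-pair re-fitting
from several seed subsets. Everything is deterministic. Self-alignments score
exactly 1.0; ideal helices vs. sheet pairs of equal length score well below
the 0.4 significance threshold.

## What the fixtures emulate — and what they do not

The generators produce ideal α-helices (rise 1.5 Å, radius 2.3 Å,
100°/residue), antiparallel strand pairs (4.8 Å apart, rise 3.3 Å, 4-residue
turns), and libraries of coordinate-jittered copies (σ = 0.3 Å) carrying
native-like sequences. Native sequences follow a fixed positional base
pattern (A/L/E/K on helices, V/I/T/Y on strands) with 30% seeded
substitutions from a biased composition — the pattern is what gives
structure-based profiles a positional signal shared across library members,
the way real structural analogs share conserved positions.

The fixtures exercise distance binning, burial counting, alignment, profile
accumulation and the full optimization loop. They are *not* physically
realistic: no loops beyond the minimal turn, no packing of side chains, no
realistic burial spectrum (a lone helix is a rod — its interior/terminal
burial contrast is real but narrow), and analog libraries whose members are
far more similar to the target than real CATH/PDB neighbours would be.
Passing tests on fixtures therefore establishes the correctness of the
machinery — tables equal their oracles, alignments behave, the optimizer
optimizes reproducibly — not the biological quality of evolved sequences on
real proteins, which depends on potentials derived from a real, diverse
reference library.

Problem sizes in the tests (60-residue targets, 10-member libraries, 200
calibration sequences, shortened cooling ladders for optimizer tests) were
chosen as the smallest sizes at which every statistical assertion has
comfortable margin; the production schedule is exercised arithmetically
(6915 levels) rather than by running 1.4×10⁷ iterations in a test.

## Numerical choices and degenerate inputs

* +1 pseudocounts in all count tables; +0.5 per class in profile rows.
* Contact reference shell: the outermost 0.5 Å bin; shell midpoints are used
  for the distance scaling.
* Burial bin edges: `type = 1` (inverse-CDF) quantiles, deduplicated; on a
  reference set with few distinct counts the alphabet degrades gracefully to
  fewer states.
* Anti-clustering variance ≤ 1e-12 ⇒ that class's z is 0 (covers n_c ∈
  {0, 1, L}); the Monte Carlo null is used for windows > 1.
* Chains shorter than 10 residues are refused as degenerate everywhere.
* Missing Cβ on a non-glycine is rebuilt from N/CA/C at ideal tetrahedral
  geometry (1.53 Å); residues without Cα are dropped with a warning; altLoc
  keeps the highest occupancy (ties: first in file); first MODEL only;
  residues are re-indexed 1..L in file order, ignoring author numbering and
  insertion codes.
* Side-chain centroids are unweighted means of side-chain heavy atoms
  (Cβ included); mass weighting is available via `read_structure(...,
  mass_weighted = TRUE)`.
* Ties in the DP traceback resolve diagonal-first, then up; with a fixed seed
  the whole pipeline is deterministic.

## Known limitations

* The backbone is frozen; nothing here models backbone relaxation or
  side-chain packing.
* The aligner is a heuristic: it matches purpose-built aligners on
  self-similar and clearly-dissimilar cases (the regimes the profile builder
  depends on) but is not guaranteed optimal on hard remote-homology pairs.
* Weight calibration optimizes a separability proxy on decoys, not fold
  recognition performance downstream.
* Multi-chain complexes, mmCIF input, and running STRIDE itself are out of
  scope; STRIDE output is consumed, and the fixture generator writes
  ASG-format annotations for synthetic structures.
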