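---
title: "Assembling a mitogenome with a duplicated control region: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling a mitogenome with a duplicated control region: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Parrot mitochondrial genomes — Amazona mitogenomes in particular — carry a
duplicated control region: two nearly identical copies (CR1, CR2), each with
a low-complexity tandem-repeat tract, separated by a short spacer. On
short-read data this duplication defeats ordinary assemblers: the two copies
share almost every k-mer, paired-end inserts cannot bridge from one copy to
the other, and the tandem repeats make copy number locally unresolvable.
`mitoforge` implements the computational core of a hybrid strategy for this
situation: a supervised, reference-assisted de Bruijn k-mer walkthrough in
which every bifurcation of the k-mer graph is arbitrated against independent
evidence — PCR product sizes, paired-end insert consistency, and long reads
spanning the duplication — and a fork that no evidence can settle is reported
as AMBIGUOUS rather than guessed at. Companion modules cover the surrounding
computations of a mitogenomics study: NUMT discovery with an identity
threshold calibrated from a mitogenome panel, capture-bait tiling, consensus
calling, variant-density tracks, nucleotide diversity, pairwise identity, and
Fitch parsimony statistics on fixed topologies.

## The walkthrough assembler

Canonical 23-mers are counted in the raw short reads. Because whole-genome
libraries cover the mitogenome one to two orders of magnitude deeper than the
nuclear background, the count spectrum is bimodal; a k-mer is *mito-class*
when its count reaches the geometric mean of the two coverage modes (supplied
or inferred from the histogram). The geometric mean is this package's choice
of threshold: it sits at the point where the two Poisson-like mixture
components have comparable tail mass, and it is configurable.

The walk is seeded at the first k-mer of the reference's 12S rRNA that is
present mito-class in the read table, and extends rightward base by base
while exactly one successor k-mer is mito-class. Extension runs around the
full circle; circularization is declared exactly when the frontier k-mer
returns to the seed. (Seeding at 12S and extending to closure is equivalent
to bidirectional extension on a circular molecule and gives a single,
unambiguous stop condition.) The final sequence is normalized to the
lexicographically minimal rotation over both strands, so independently
assembled circles can be compared with `identical()`.

### Fork arbitration

At a bifurcation (two or more mito-class successors) the assembler
enumerates candidate continuations through subsequent sub-forks — a beam
search, capped at 256 live candidates and bounded by `max_branch_depth`
(default 5,000 bp, enough to span a control-region-scale duplication; the
working depth for evidence is one insert reach plus two read lengths).
Three checks prune candidates as they grow:

* **Read-pair phasing.** Every pair of positions `(a, b)` within one
  phasing reach (insert mean − 2 SD, default 270 bp) must be jointly
  covered either by one exactly placed read or by the two mates of a placed
  fragment whose implied insert lies within mean ± 4 SD. A chimeric join
  between the two CR copies leaves the straddling position pair linked by
  nothing — reads of either copy mismatch on one side of the join — while
  on the true path tens of fragments link every such pair at 100×
  coverage. This is the check that phases the substitution differences
  between CR1 and CR2. The reach is deliberately 2 SD below the insert
  mean: at spacing equal to the reach the expected number of linking
  fragments is still ≈25, so a true path is never starved by sampling
  noise, while joins wider than the reach fall through to the long-read
  vote below. Adjudication trails the candidate frontier by one read
  length plus 16 bp, because a linking fragment's rightmost mate must fit
  inside the candidate string before the pair can testify.
* **Long-read consistency.** Each long read is anchored to the contig once,
  by the modal k-mer diagonal over a 1.2 kb window (the homologous CR copy
  always attracts a competing diagonal from shared k-mers, so anchoring
  requires a 1.5× vote margin, and the winning diagonal is verified by
  masked positional identity ≥ 0.85 over the anchor window — the true
  diagonal adds unique-flank and allele k-mers on top of the shared ones,
  and a diagonal captured by the homologous copy fails across the unique
  flank). Because the simulator's
  long-read error process is substitution-only, the anchor diagonal is
  constant for the rest of the walk, and a candidate is compared
  *positionally* against the read over the read's solid (k-mer-supported)
  positions. A candidate must reach 0.8 identity against some informative
  read, both over its full extent and over its trailing 128 bp on their
  own — the tail window matters because a wrong tandem-repeat exit near
  the end of a long candidate still averages above the floor overall.
  Only reads whose full-window identity passes the floor may veto via the
  tail, so a read whose anchor drifted cannot kill branches it does not
  match at all. Wrong copy numbers shift all downstream sequence out of
  register and collapse to ≈0.25 identity; true candidates sit near 0.99
  because the solidity mask hides most sequencing errors (at 10% error
  only ≈20% of read positions are solid — a base must sit inside a
  ≥ k error-free run — which is also why identity checks demand a few
  dozen comparable positions rather than long stretches).
* **Amplicon lengths.** If both primer sites of an amplicon land on the
  extended contig, the implied product length must not exceed the expected
  length by more than the tolerance (default 10%, gel-estimate precision).
  Under-length products do not disqualify a branch mid-assembly: a primer
  site drawn from one CR copy has a substantial chance (0.98^24) of an
  exact false match in the other, not-yet-assembled copy, which would imply
  a spuriously short product. The completed circle is checked in both
  directions.

If the surviving candidates disagree only in their first bases — a CR
substitution site beyond read-pair reach — the anchored long reads vote:
each read backs the branch its own bases match best over a 256 bp
unmasked window (errors cancel between candidates compared at identical
read positions), and only a strict majority eliminates branches. With three spanning reads
at 10% error the probability of a wrong majority at a site is ≈3·10⁻³;
without long reads such forks stay AMBIGUOUS, which is the designed
behavior rather than a failure mode: the evidence genuinely cannot decide.
The committed extension is the longest common prefix of all surviving
candidates, so anything not yet adjudicated is re-examined at the next
fork. Ties are never broken by k-mer counts.

### Validation

A circularized assembly is re-checked three ways: anchored positional
identity of every long read (solid regions only, pass at median ≥ 0.8),
implied amplicon lengths within tolerance, and coverage continuity (no
k-mer start on the circle absent from the read table). Constructed defects
— a 500 bp deletion, a 50 bp novel insertion — trip the amplicon and
coverage checks respectively.

## What the generator emulates — and what it does not

`generate_mitogenome()` lays out a 18.6 kb circle with 13 protein-coding
genes plus one pseudogene, 22 tRNAs plus one pseudogene, two rRNAs, and two
1.1 kb control-region copies at 0.98 identity, each containing an exact
12 bp × 14 tandem-repeat tract, separated by a 210 bp spacer-like element.
Divergence between the copies is substitution-only, which keeps the target
identity exactly controllable; NUMT degradation uses substitutions and
indels at 10:1 so the gapped aligner is genuinely exercised. Sizes follow
typical avian mitogenomes with the duplication added; the true length of
the study species' mitogenome is not published, so the default length is a
configurable choice, not a claim.

Reads are simulated with Gaussian fragment lengths in FR orientation
(error-free by default) and Gaussian long-read lengths averaging 3.5 kb
with substitution-only errors at a configurable rate (default 10%).
Platform-specific quality models, indel-dominated long-read error profiles,
chimeric reads, and coverage biases are deliberately out of scope. Two
consequences matter for interpretation: the long-read anchoring shortcut
(constant diagonal) relies on the substitution-only process — real
indel-rich reads would need banded alignment in its place — and passing
tests on this generator demonstrates the logic of evidence arbitration, not
robustness to every artifact of real instruments. The panel generator
(`simulate_panel()`) likewise derives related sequences by substitution
only, so panels are intrinsically aligned; real consensus sequences must be
aligned externally before the diversity statistics apply.

## NUMT discovery

The mitogenome (doubled, so hits may cross the origin) is searched against
the nuclear sequence on both strands by exact-word seeding (word 11),
greedy diagonal clustering, and banded Smith–Waterman extension with affine
gaps, using blastn-style scores (+2/−3, gap open 5, extend 2) and
Karlin–Altschul statistics (λ = 0.625, K = 0.41) for e-values; hits above
`evalue_max` (default 10⁻⁴) are dropped. Identity is computed over columns
where both sequences carry a base. The identity *ceiling* for accepting a
hit as a genuine NUMT is not fixed but calibrated: the largest pairwise
global-alignment identity among the available mitogenomes (96.8% for the
two closest species in the study this design follows) — anything more
similar to the mitogenome than two sister species are to each other is
taken to be misassembled mtDNA, not a nuclear copy. Identical matches
(same coordinates and strand) count once; merging of merely-overlapping
hits is deliberately not done by default, since the search runs unfiltered
for low-complexity sequence and the right merging policy is data-dependent.

## Diversity and parsimony statistics

Pairwise difference lists skip columns with N and count gap-vs-base only on
request; 100 bp block counts keep the final partial block raw, with block
boundaries at column 0 — the simplest auditable convention, matching how
per-window disagreement tracks are drawn around a mitogenome circle.
Nucleotide diversity is the mean over unordered pairs of the per-pair
proportion of differing comparable sites (pairwise deletion of non-ACGT),
the average-pairwise-difference estimator; whether to include the control
region is the caller's choice of input columns. Fitch lengths are computed
by the standard bitmask postorder pass with missing data as the full state
set; polytomies are resolved deterministically before scoring, and the
result is invariant to rooting. CI = M/S, RI = (G−S)/(G−M), and the
rescaled index RC = CI·RI are reported for all sites and for
parsimony-informative sites side by side, since published values rarely say
which convention was used; indices are NA when S = 0.

## Numerical and scale choices

Default problem sizes keep the full test suite and the acceptance runs
desk-sized: 18.6 kb genomes at 100× paired coverage with three spanning
long reads for the assembly benchmark (20 replicates with and 20 without
long reads), 200 kb nuclear backgrounds with eight planted copies for the
NUMT benchmark (20 replicates), 100 random ≤6-taxon fixtures for the
exhaustive-parsimony cross-check, and 1,000 random difference sets for the
density-conservation property. All randomness flows through explicit
integer seeds; identical seeds give byte-identical outputs, including the
pipeline manifest checksums.

## Known limitations

* The simple read placer is gapless; individuals with indels relative to
  the reference need externally produced alignments.
* Long-read arbitration assumes substitution-dominated errors (see above).
* The NUMT search is not a drop-in reimplementation of any specific BLASTN
  version; hit counts depend on the recorded scoring configuration.
* tRNA gene discovery is annotation transfer only; covariance-model
  scanning is out of scope.
* Consensus calling is unweighted majority with N at ties — conservative,
  and intentionally binary for downstream difference counting.
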