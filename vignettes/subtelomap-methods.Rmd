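---
title: "Methods: simulating, assembling and calling subtelomeric optical maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, assembling and calling subtelomeric optical maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(subtelomap)
```

## The problem

The distal ~500 kb of human chromosome arms is dominated by
evolutionarily recent segmental duplications ("paralogy blocks") and
punctuated by reference gaps of estimated size (runs of N adjacent to
the telomere). Short reads cannot resolve these regions; optical
genome mapping can, because single DNA molecules of 150 kb and longer,
fluorescently labelled at every Nt.BspQI nick site, span the
duplicated material and connect the chromosome end to arm-specific
1-copy DNA. `subtelomap` implements that analysis as a closed loop:
it simulates nick-labelled molecules from block-structured synthetic
haplotypes, assembles them into consensus maps, anchors the consensus
to reference arms, measures how far each haplotype extends relative to
the reference end, classifies the telomere-adjacent gap, detects
paralogy blocks from their nick-spacing patterns, and tests block
frequencies across super-populations.

A label map — an ordered vector of label positions along a DNA
segment — is the single currency passed between all stages.

## Alignment model

Two label maps are aligned by dynamic programming over *chunks*. A
chunk extends the alignment by one matched pair of labels, skipping up
to `max_skip` labels on either side, and scores

$$ r \;-\; \frac{(d_q - d_r)^2}{2\,(\mathrm{cv}^2 d_r^2 + 2\,\sigma_j^2)}
   \;-\; n_q\,\lambda_{fp} \;-\; n_r\,\lambda_{fn} $$

where $d_q, d_r$ are the query and target inter-label distances,
$\mathrm{cv}$ is the multiplicative sizing error per interval,
$\sigma_j$ the additive per-label jitter, and $n_q, n_r$ the skipped
labels on each side. This is the standard Gaussian-sizing-error,
per-label-penalty formulation for restriction/nick map alignment; the
penalties default to $-\log$ of the label error rates
($\lambda_{fp} = \lambda_{fn} = -\log 0.1 \approx 2.3$) with a match
reward of 3. Two modes share the same recurrence: *fit* (global in the
query, local in the target — used to place a block pattern or a
molecule inside a larger map) and *overlap* (both ends free — used for
molecule dovetails, arm anchoring and consensus merging). Scores are
rounded to $10^{-9}$ before comparison and ties break toward the
lowest target offset, then the forward orientation, so runs are
bit-reproducible. The DP core is C++ (Rcpp); a brute-force enumeration
oracle in the test suite checks it exhaustively on all small maps.

`min_aligned_labels = 9` and `min_score = 15` were calibrated on
simulated unrelated maps (30–40 labels at the default label density)
such that no chance dovetail is accepted; the unit tests re-check a
seeded null set at every run.

## Assembly

Assembly follows overlap–layout–consensus:

1. **Overlap graph.** All molecule pairs are overlap-aligned. Because
   instrument output has unknown strand, a union–find with parity
   fixes one global orientation per component (processing edges in
   descending score); edges that contradict the assignment, triangles
   whose offsets disagree by more than 10 kb (lowest-scoring edge
   dropped), directed cycles (minimum-score feedback arcs) and
   transitively redundant edges are removed, leaving a DAG per
   component.
2. **Layout.** The highest-weight path (sum of edge scores) seeds the
   layout; remaining molecules attach through their best edge to a
   placed molecule.
3. **Consensus.** Rigid placements accumulate each molecule's sizing
   stretch (about 1–2 kb over 300 kb), which would blur label piles.
   Molecules are therefore walked left to right and *projected*
   piecewise-linearly through their alignment to the running consensus
   of already-projected molecules; a projection may not move a
   molecule more than 20 kb from its graph placement, which stops
   chance matches from relocating it. Pooled labels are clustered by
   repeatedly taking the densest window of width
   `optical_resolution_bp` (1.5 kb) — a plain gap-split would let
   scattered false-positive labels chain adjacent site clouds
   together. A cluster becomes a consensus label when its molecule
   support reaches `support_fraction` (0.3) of the local depth: true
   sites arrive at ~90% support, false positives at ~1–2 molecules
   against a depth of 60.
4. **Refinement and extension.** Each member molecule is re-aligned to
   the consensus and re-projected; labels beyond either end with
   sufficient support extend the map. Iterated to a fixed point (no
   label moves > 100 bp, none added or removed) or five rounds.
5. **End evidence.** Molecules cannot extend past a telomere, so
   telomere-terminal molecules truncate at the same coordinate. If
   enough telomere-labelled member ends agree (and they are unimodal —
   a heterozygous assembly has two such modes and must not be capped
   at their median), the consensus is capped there and the terminus
   marked confirmed; a pileup of ordinary molecule ends at the map end
   confirms a terminus the same way.
6. **Diploid splitting.** A heterozygous arm whose alleles differ in
   terminal length piles up the shorter allele's molecule ends
   *strictly inside* the joint consensus while the longer allele's
   molecules span through. A pileup with at least
   `max(10, 0.35 x depth)` co-terminating molecules, at least five
   spanning molecules and no matching start pileup (which would
   indicate a breakage site, e.g. an inverted nick pair) splits the
   consensus into the shorter allele (truncated at the pileup) and the
   longer one; shared molecules ending before the pileup serve both.
   These thresholds assume the study's 60x coverage.
7. **Merging.** Two consensus maps merge when their dovetail alignment
   matches at least `merge_span_fraction` (0.8) of the labels inside
   the implied shared span on both maps and neither map's *confirmed*
   terminus would be overhung by more than the reporting resolution.
   The second condition is what keeps a 45-kb-longer haplotype from
   being absorbed into its sibling, since the shorter allele's
   terminus is end-confirmed. Merging is idempotent.

Components with fewer than three molecules are reported as failed to
assemble, never imputed.

## Arm calling

A contig anchors to the reference arm whose 1-copy interval captures
at least `min_aligned_labels` matched labels, provided the best arm
outscores the second best by `anchor_margin` (1.2); otherwise it is
left unanchored — paralogy blocks shared between arms must not drive
an assignment. The contig's telomeric terminus is projected into
reference coordinates through an affine (scale + offset) fit of the
matched pairs; a consensus map inherits its backbone molecules'
overall sizing error, and the slope term absorbs it (the slope is
constrained to [0.9, 1.1] and falls back to offset-only for thin
alignments).

Each anchored call carries two signed lengths:

* `extension_bp` — terminus minus the end of real (non-N) reference
  sequence (`tel_end_bp`);
* `gap_correction_bp` — terminus minus the annotated chromosome end
  including the terminal N pad (`arm_end_bp`), the convention of the
  published per-arm summary tables (negative = the reference gap is
  too large).

Absolute values under `gap_resolution_bp` (10 kb) are reported as 0;
larger calls are rounded to 5-kb multiples, the granularity at which
such tables print. The gap assessment is EXTEND (past the annotated
end), SUPPORTED (terminus inside the gap, or matching a gapless end),
DELETE (ends at or before the gap start), INACCURATE (anchor aligns
but the distal reference pattern conflicts), or NO_CALL.

Telomere confirmation requires `telomere_confirm_k` (3)
telomere-labelled molecule ends within tolerance of the terminus and
no labelled end clearly beyond it. Inverted nick pairs — opposing-strand
nick sites within `inp_distance_bp` (1 kb; the threshold is ours, the
phenomenon is double-strand breakage at closely opposed nicks) — are
scanned on stranded in-silico digests; simulated molecules spanning an
INP break with probability `p_break` (0.9), which measurably reduces
how often contigs reach the telomere.

Haplotype clustering is single linkage: two contigs link when their
alignment matches at least 80% of the labels in the shared span on
both maps *and* their terminal lengths differ by less than the 10-kb
resolution; cluster 1 is the largest. An arm is HIGH-variability when
the minor haplotypes' combined share strictly exceeds 10% — exactly
10% is LOW, reading "less than 10% ... low variability" as a strict
bound on the HIGH side.

## Block detection and population statistics

A paralogy block is characterised purely by its nick-spacing vector.
Detection fit-aligns each pattern (both orientations, repeatedly with
matched labels masked) and accepts non-overlapping hits with matched
label fraction >= 0.75 and mean per-label score >= 2; patterns with
fewer than three labels are only analysed inside named groups (e.g.
"B1-2"). Presence is one indicator per genome-arm (a diploid double
carrier counts once). Frequencies divide carriers by genomes with at
least one anchored map for the arm. Differences across the five
super-populations are tested with one-way ANOVA on the 0/1 indicators
(`stats::aov`), Bonferroni-corrected across the family of per-arm
tests for that block, with the family size reported alongside.

## The generator and what it does and does not emulate

The synthetic-data generator *is* the study design: 154 diploid
genomes in five super-populations (42/30/30/24/28), Nt.BspQI-style
labelling (GCTCTTC, label at the motif start) with 10% false-positive
and 10% false-negative label error, molecules above 150 kb at 60x
mean coverage, 500-kb windows with a 1-copy anchor on the centromeric
side, terminal N gaps, optional telomere end labels (a boolean flag on
molecules whose distal end reaches the true telomere, standing in for
CRISPR-Cas9 telomere tagging), and INP breakage. Molecule lengths
follow a shifted exponential (minimum 150 kb, mean 300 kb) truncated
at the map ends. Sizing noise is multiplicative Gaussian per interval
(CV 0.02) plus 300 bp additive jitter — magnitudes chosen so that
10-kb terminal differences remain resolvable, since no published
values exist for them; labels closer than the 1.5-kb optical
resolution merge to their midpoint. The false-positive process is
homogeneous Poisson with rate solved from the target FP fraction. The
1-copy anchor pattern of every arm is seeded from the arm name and
rejection-sampled so that no library block pattern fit-aligns into it;
the eight-block default library is likewise collision-checked.

Not emulated: image-level noise and stretch fields, chimeric
molecules, sister-arm paralogy at the sequence level, acrocentric
p-arms, D4Z4-type tandem repeat arrays, or two-channel/dual-enzyme
labelling. Passing tests therefore demonstrate correct recovery under
the stated error model, not robustness to every artefact of real
nanochannel-instrument data.

## Numerical choices and reproducibility

All coordinates are 0-based half-open; arm-local maps always increase
toward the telomere (p arms are mirrored on extraction), so extension
arithmetic is identical for p and q arms. One master seed fans out to
per-stage child seeds through a fixed affine map modulo $2^{31}-1$, so
any stage can be re-run in isolation; every simulated-data function
saves and restores the global RNG state. Degenerate inputs: empty maps
align to nothing; an all-identical presence vector yields an NA-flagged
ANOVA row rather than a test; maps shorter than the minimum molecule
length refuse to simulate.

Problem sizes in the shipped tests and acceptance script are scaled to
single-arm cohorts (one to five genomes per run, ~100–250 molecules
per genome-arm at full 60x coverage) — the per-genome computation is
identical to a full cohort, which is simply this loop over 154
genomes.

## Known limitations

* Alleles differing only *below* the 10-kb resolution are one cluster
  by design; alleles differing only by a pure terminal truncation are
  separable only through the end-pileup signal, which needs tens of
  co-terminating molecules (it is reliable at 60x, not at low
  coverage).
* The anchor margin makes arm assignment conservative: a contig whose
  1-copy region is ambiguous between two arms is dropped rather than
  guessed, mirroring the published analysis's unassigned contigs.
* Block hits shorter than three labels cannot stand alone; partially
  eroded terminal blocks may fall under the 0.75 match fraction and go
  uncounted.
* The DP aligner is exact under its chunk model but the model itself
  assumes independent Gaussian interval errors; strongly correlated
  stretch would require per-molecule scale estimation beyond the
  affine projection used at anchoring.
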