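---
title: "Directional substitution asymmetry and proteome composition: methods"
author: "OrthoAsym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional substitution asymmetry and proteome composition: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OrthoAsym)
```

## The question the package answers

Bacteria adapted to high hydrostatic pressure (piezophiles, e.g. deep-sea
sulfate reducers of the genus *Desulfovibrio*) can differ from close
non-piezophilic relatives in the amino-acid composition of their
proteomes. OrthoAsym implements the comparative machinery used to detect
such compositional adaptation between two proteomes: which residues are
preferentially lost, which preferentially gained, and whether the
whole-proteome composition sets an organism apart from its relatives.

The core quantity is the **directed substitution matrix** `M`: over every
gap-free column of every aligned ortholog pair, `M[a, b]` counts positions
where the reference organism carries residue `a` and the comparison
organism residue `b`. The diagonal holds conserved positions. For an
unordered residue pair `{a, b}` the two directed counts `x = M[a, b]` and
`y = M[b, a]` are, under neutral divergence, two realisations of the same
exchange process, so their split is expected to be 50:50. Deviation is
tested with a one-degree-of-freedom goodness-of-fit statistic,

    chi2 = (x - y)^2 / (x + y),

and the residue on the receiving end of the net flow is reported as the
gaining direction. Following the original analysis style, the default
significance threshold is a raw `p < 0.0005` with no multiple-testing
correction across the 190 pairs; Bonferroni and Benjamini-Hochberg
adjustments are available behind the `correction` argument, and an exact
two-sided binomial test behind `method = "binomial"`.

## Orthology and alignment

Ortholog pairs are called by reciprocal best hits (RBH): every protein of
proteome A is globally aligned against every protein of proteome B
(Needleman-Wunsch with affine gaps; BLOSUM62, gap open 11, gap extend 1 —
the BLASTP defaults), and a pair is retained only when each member is the
unique top-scoring hit of the other. A heuristic E-value pre-filter is a
search optimisation, not part of the statistic, so exact all-vs-all
scoring replaces it at desk scale; an optional raw-score floor
(`scoreFloor`) is available. Equal-score best hits make "the best hit"
ill-defined, so ties disqualify the gene rather than picking a winner
arbitrarily.

Retained pairs must pass `identity >= 30%` and `coverage >= 70%` **on
both sequences** (the stricter reading; coverage on one side only can be
requested by lowering the other threshold to zero). Identity is defined
over gap-free alignment columns: the ambiguity letter X (lenient mode)
occupies a column and enters the denominator but never counts as
identical, and its columns are excluded from substitution counting, so
only the 20 canonical residues ever reach the matrix.

Alignment is delegated to `Biostrings::pairwiseAlignment`, which uses the
same affine convention (a gap of length L costs `open + L * extend`) and
a deterministic traceback; the test suite checks optimality of its scores
against an exhaustive enumeration of all alignments for short sequences
rather than trusting either implementation.

## Composition clustering

Per-proteome amino-acid frequency vectors are compared by the Pearson
correlation distance `d = 1 - r` (range 0 to 2; the alternative
`(1 - r)/2` convention is a trivial rescaling that does not change a
neighbor-joining topology). Trees are built by the Saitou-Nei
neighbor-joining algorithm with the Studier-Keppler Q criterion,
implemented in the package so that its numerical conventions are
explicit:

* ties in Q are broken by the lowest pair of current label indices,
  making join order deterministic;
* negative branch lengths are clamped to zero with the deficit
  transferred to the sister branch, a common NJ practice;
* the output is an unrooted `phylo` object with ape-compatible node
  numbering.

On exactly additive distances NJ provably recovers the generating tree;
the tests exercise this guarantee on random 4-8 taxon trees and
cross-check topologies against `ape::nj`.

## Genome descriptors

* **GC / GC3** — GC is the G+C fraction over all positions; GC3 restricts
  to every third codon position pooled over CDSs. Sequences whose length
  is not a multiple of 3 are excluded from GC3 (error in strict mode). A
  terminal stop codon can be dropped (`excludeStop`) since stops encode
  no amino acid; the default keeps it, and at genome scale the difference
  is far below a percentage point.
* **Isoelectric point** — net charge is a sum of Henderson-Hasselbalch
  terms for D, E, C, Y, H, K, R side chains plus the two termini, with
  the EMBOSS pKa set (configurable); the pI is found by bisection on
  pH 0-14 to |charge| < 1e-4. A proteome's pI is the unweighted mean over
  sequences.
* **Signatures** — tetranucleotide frequencies are counted in overlapping
  windows on the given strand (optionally pooled with the reverse
  complement, off by default) and normalised to sum to 1; codon usage is
  pooled over all CDSs and expressed as RSCU (observed count times family
  size over family total) for the 61 sense codons. Both vectors are
  comparable across organisms with the same Pearson correlation distance.
* **COG outliers** — category counts become within-organism proportions;
  a focal organism's category is flagged when its proportion lies more
  than two sample standard deviations (n-1 denominator) from the mean of
  at least two reference organisms. With zero reference variance any
  deviation is flagged, equality is not — the rule's natural limit.

## Differential spot abundance

Spot volumes from two growth conditions are normalised per gel (volume
over the gel's total), replicates averaged per condition, and the
differential abundance (DA) is the larger over the smaller relative
volume. Significance uses the **inclusive** rule `DA >= 1.5`: the
packaged published tables contain a row printing DA exactly 1.5, so a
strict inequality would contradict them (strictness is a flag). A spot
quantified in only one condition is a qualitative presence/absence
difference and is kept as significant with undefined DA. The `(+/-0.2)`
uncertainty printed beside the published DA columns is stored as metadata
and unused in computation.

## The synthetic-data generator

Every stage is testable without external downloads because the generator
plants known truth:

* **Ortholog proteome pairs** (`simulateOrthologProteomes`) — ancestral
  proteins are drawn i.i.d. from a stated composition (default: Swiss-Prot
  average frequencies; the real ancestral composition is unknowable, and a
  standard background makes composition recovery meaningful). Each of the
  two descendant branches substitutes sites independently with
  probability `subRate/2` (single hit, no back-substitution: the
  downstream analysis counts site states, not histories), drawing targets
  from a symmetric base-exchange weight matrix. Directional bias
  multipliers (`biasPairs`, e.g. `c("K>R" = 2)`) scale ordered exchanges
  on the branch leading to proteome B — a direction must live on one
  branch for the directed matrix to be asymmetric in expectation, and
  placing it on the comparison organism's branch matches how the matrix
  is read. Indels are single-residue (the analysis discards gapped
  columns, so indel geometry only exercises gap handling), paralogs are
  diverged duplicates (three times the substitution rate) to exercise
  best-hit ties, and orphans are unpaired genes. The default
  `subRate = 0.2` yields roughly 20% substituted positions, a divergence
  at which RBH is unambiguous but substitution counts are plentiful.
* **CDS sets** (`simulateCdsSet`) — every sequence starts with ATG;
  later codons draw their third position G/C with probability equal to
  the GC3 target. The invariant start codon contributes one fixed G per
  sequence, so the degenerate targets (0 and 100) hold exactly at all
  non-start codons and the set's GC3 converges to the target as length
  grows.
* **Spot tables** (`simulateSpotTable`) — log-normal base volumes shared
  by both conditions, planted fold changes on the second condition, and
  mean-corrected multiplicative log-normal noise. Note that total-volume
  normalisation makes recovered DA differ from the planted fold by the
  planted spot's mass share (the condition totals shift); the tests
  compare against an oracle that accounts for this.

What the generator does **not** emulate: site-rate heterogeneity,
correlated substitutions within genes, codon-level selection,
multi-taxon phylogenetic structure, or gel artefacts (saturation,
co-migration). Passing tests therefore demonstrate correctness of the
machinery and calibration of the statistics under idealised divergence,
not robustness to every property of real data.

## Numerical choices and validation scale

* The chi-squared test is used without Yates continuity correction. Its
  p-values track the **mid-p** exact binomial within 0.005 across the
  packaged table (mid-p is the standard calibration when comparing a
  discrete exact test with an asymptotic statistic); the plain exact
  binomial agrees wherever p is small enough to matter, but its
  discreteness inflates p by up to ~0.1 at near-even counts around 30,
  which is why the plain exact test is offered as an option rather than
  used to mimic the chi-squared values.
* Simulation scales used by the validation suite: type-I error uses 50
  bias-free pairs of 100 proteins x ~300 residues; power uses 100
  replicates of 2,000 proteins x ~300 residues with a symmetric K/R
  exchange weight of 6.85 and a K-to-R multiplier of 2.42, which sizes
  the two directed counts to a total near 4,000 with a ratio near 1.37 —
  the effect size of the strongest published exchange; composition
  clustering uses two groups of four organisms whose generating
  compositions differ by +40% on the gaining residues (A, H, R, T) and
  -25% on the losing ones (D, E, K, N, S, Y), with 5% log-normal
  per-organism jitter. These sizes make the whole suite run in a few
  minutes while keeping every Monte-Carlo bound comfortably away from
  its threshold.
* All randomness flows from a single integer seed per simulation; the
  same configuration and seed reproduce byte-identical FASTA/TSV output.

## Known limitations

* The published per-residue replacement percentages are not reproducible
  from any stated formula; `replacementSummary` defines its net-excess
  percentage explicitly (net excess over the residue's full row total)
  and the package makes rank statements only.
* RBH returns one-to-one pairs only; genuine many-to-many ortholog
  groups are out of scope, and paralogs are handled solely by the
  tie-disqualification rule.
* The pipeline begins at quantified spot volumes and proteome/CDS FASTA;
  spot detection, image registration, genome annotation and
  mass-spectrometry identification are upstream of it.
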