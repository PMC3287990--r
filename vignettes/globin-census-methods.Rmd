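---
title: "Methods: globin identification, classification and census"
author: "globinCensus authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: globin identification, classification and census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(globinCensus)
```

# The problem

A globin census over many fungal genomes asks, for every candidate
protein: does it carry a genuine myoglobin-fold globin domain; which
family (F, S, or T) does that domain belong to; what is the protein's
domain architecture; where does the globin domain begin and end; and how
do the per-protein calls aggregate into per-taxon presence counts? This
vignette documents the models and procedures behind each stage, the
tunable parameters and their defaults, the synthetic data the package
tests itself against, and the limits of what those tests show.

# Fold validation

## Anchoring

A query is aligned to an annotated reference template with a
deterministic pairwise alignment: BLOSUM62, affine gap penalties (open
11, extend 1), end gaps free. End-gap-free ("overlap") alignment rather
than a strictly global one is a deliberate choice: flavohemoglobins are
chimeric proteins of roughly 400 residues in which the 150-residue
globin domain is one of three domains, and a strictly global alignment
against a single-domain template would spread terminal gap cost across
the reductase moiety. With free end gaps the template anchors cleanly
inside the chimera while the alignment within the anchored region is the
ordinary global optimum. The alignment transfers the template's
helix-coordinate labels (A8 ... H19, CD1, FG4, F8) onto the query; a
label whose template column pairs with a gap is reported as unaligned.

## The checklist

The myoglobin fold is operationalized as 36 conserved,
solvent-inaccessible positions: 33 intra-helical, the two inter-helical
corners CD1 and FG4, and the invariant proximal His at F8. The first 35
are scored for hydrophobicity; F8 is a hard identity requirement. For
the truncated 2/2 fold the A- and E-helix labels are dropped (those
helices are vestigial in T globins) and the remaining positions are
scored the same way.

Two conventions here are package decisions, because the source method
names no hydrophobicity alphabet and no passing fraction:

* hydrophobic set `{A, V, L, I, M, F, W, Y, C}` — the standard apolar
  side chains plus cysteine, which buries readily;
* "predominantly hydrophobic" is implemented as a configurable fraction
  threshold with default 2/3, with unmapped checklist positions counted
  as failures.

## The shuffle-null Z-score

The alignment raw score $S$ is standardized against scores of
composition-preserving (Fisher–Yates) shuffles of the query aligned to
the same template:

$$ Z = \frac{S - \widehat{\mu}_{\mathrm{null}}}{\widehat{\sigma}_{\mathrm{null}}} $$

Acceptance requires $Z > 6$ (configurable; 6 is the stated default
threshold of the profile-search method this stands in for), His at the
mapped F8, and the hydrophobic fraction at or above its threshold — a
conjunctive rule, so each criterion can veto independently. The default
number of shuffles is 200 (minimum 30). Because the null moments are
Monte-Carlo estimates, $Z$ itself carries sampling noise of roughly
$Z/\sqrt{2n}$; at 500 shuffles a self-match scoring $Z \approx 120$
varies by several units across seeds while its accept/reject decision
never flips. Tests therefore assert decision stability and a small
coefficient of variation rather than an absolute spread.

A degenerate query (for example a homopolymer) makes every shuffle
identical and the null variance zero; this is signaled as an error
rather than silently scored.

## Family assignment and trimming

One template per family (GLB3 for F, SGB for S, GLB2 for T) is
evaluated and the family of the highest-$Z$ accepted template wins; if
none is accepted the protein is a non-globin. Accepted domains are
trimmed by the fixed rule: start 11 residues before the mapped B10,
end 15 residues after the mapped H8, clamped to the sequence. If B10 or
H8 is unaligned, trimming is reported as impossible rather than guessed.

# Architecture classification

Non-globin evidence comes from three scanners:

* **cqx2 / cqx3** (FAD- and NAD(P)-binding reductase moieties): local
  alignment against packaged templates with per-kind score thresholds of
  60. Calibration on random 400-residue sequences puts the random local
  score maximum near 52 while true hits diverged to 40% identity score
  above 110, so the threshold sits in a wide margin (false-positive
  rate well under 5%).
* **LRR**: the 11-residue motif `LxxLxLxxN/CxL`; three or more tandem
  matches merge into a single hit.
* **Signal peptide**: within the first 20 residues, at least one K/R in
  the first 5 followed by a hydrophobic run of at least 8.

Overlapping hits are resolved greedily by score. The ordered rule table
then assigns: F-globin + cqx2 + cqx3 → `FHb`; F-globin + cqx2 without
cqx3 (the diagnostic absence) → `FHb_incomplete`; F-globin alone →
`Fgb`; S-globin with a C-terminal extension ≥ 100 residues →
`SensorChimera`, otherwise `Sgb`; T-globin alone → `T1`, with any other
hit → `T1Chimera`; no accepted globin → `NonGlobin`. Flavohemoglobins
between 380 and 420 residues are flagged normal-length; an N-terminal
extension over 25 residues containing a detected signal peptide sets
the signal-peptide flag. Extensions are measured from the outermost
(non-signal) hits.

Two edges of the rule table are made exact here because the source
describes them only loosely: the Sgb length cutoff ("generally <260")
is a strict, configurable 260; and an S-globin that is long but has a
short C-terminal tail falls to `Sgb` — the extension test alone decides
chimerism, keeping the table total. Proteins with more than one globin
hit are reported as errors rather than forced into a class.

# Alignment ensembles

Alternative alignments of the same sequences are compared by the
overlap of their aligned-residue-pair sets: for alignments $A$, $B$
with pair sets $P_A$, $P_B$,

$$ \mathrm{overlap}(A, B) = \frac{|P_A \cap P_B|}{(|P_A| + |P_B|)/2}, $$

a symmetric score in $[0, 1]$ equal to 1 exactly when the pair sets
coincide. Each alignment's quality is its mean overlap against all
others, and the best alignment is the maximizer (ties broken by input
order). Several overlap variants exist in the consistency-scoring
literature; the mean-normalized symmetric form is fixed here because it
is bounded, symmetric and directly checkable against a brute-force pair
enumeration. The F8 column check verifies, per sequence, His identity
at the mapped F8 and membership in the majority F8 column.

# Distances, trees, bootstrap

Pairwise distances use **pairwise deletion**: a column is dropped only
for the pairs in which either row carries a gap or an `X` (missing
data), and kept for all other pairs. The observed difference proportion
$p$ is corrected for superimposed substitutions by the Poisson formula
$d = -\ln(1 - p)$, which is strictly increasing and $\ge p$ on
$[0, 1)$; $p \ge 1$ is flagged as saturated and refuses downstream tree
building rather than producing an arbitrary large value.

Neighbor joining follows the standard Q-criterion agglomeration. Two
numerical conventions: ties in $Q$ are broken by the lowest cluster
index pair (original taxa first, in input order), making the algorithm
fully deterministic; and negative branch lengths are clamped to zero by
default (a presentation convention; a flag disables it). On additive
matrices the implementation reproduces the generating path lengths to
machine precision, and it agrees topologically with an independent NJ
implementation on random matrices — both are test invariants.

Bootstrap support resamples alignment columns with replacement,
rebuilds the NJ tree per replicate, and reports for each non-trivial
bipartition of the original tree the fraction of replicates containing
it. The default is 1000 replicates; rendered trees label only supports
above 50%. Tree comparison uses the fraction of one tree's non-trivial
bipartitions present in another; a star tree has none, and is defined
to share everything with another star and nothing with a resolved tree.

# The synthetic-data generator

Every stage is tested against proteomes built from domain grammars with
known ground truth. The packaged templates are synthetic reference
sequences (not database entries): a 150-residue 3/3 globin (GLB3, F
family), a 150-residue sensor globin (SGB, S family), a 116-residue 2/2
globin lacking the A- and E-helix labels (GLB2, T family), 96- and
150-residue reductase moieties (so the three-domain flavohemoglobin
totals 396 residues, the length of the canonical bacterial FHb), five
tandem LRR 11-mers, and an 18-residue signal peptide. All globin
checklist positions carry hydrophobic residues and F8 is His by
construction.

Divergence is modeled by uniform substitutions down to a target
identity and Poisson-distributed indels of length 1–3 (default one
indel per 100 residues), with two conservation rules: annotated
positions (the globin checklist, and the motif-defining residues of the
LRR repeats) are exempt from substitution, and indels never fall within
5 residues of an annotated label, which keeps label remapping
well-defined. Signal-peptide segments are not mutated. These rules
mirror what the respective detectors rely on in real proteins —
globins conserve the fold positions, LRR proteins conserve exactly the
motif residues — and they are what makes classifier recovery a
well-posed question. Default target identities are drawn uniformly from
0.4–0.8; real divergence levels among fungal globins are not published,
so this range is a package choice covering twilight-zone to
comfortable homology.

True multiple alignments of the globin domains are derived directly
from the edit scripts (each mutation records a template-to-mutant
coordinate map), never from an aligner, so alignment-consuming stages
are tested against ground truth rather than against another tool.
Census fixtures are expanded from a stratum configuration whose
defaults reproduce published census totals exactly (165 genomes, 136
with globins, 117 Ascomycota with 109 carrying globins, 20 of 33
Basidiomycota, 21 of 29 Saccharomycotina genomes with incomplete FHbs,
two genomes with T1 globins).

What the generator does **not** emulate: real proteome sizes (hundreds
of proteins per genome) or background composition; nucleotide-level
processes; compositional biases, repeats or low-complexity regions;
profile- or structure-level signal beyond what pairwise alignment to a
single template captures. A passing recovery test therefore
demonstrates that the pipeline's logic is correct and its thresholds
are mutually consistent at realistic divergence — not that its
sensitivity matches a structure-profile search on real fungal
proteomes.

# Problem sizes and reproducibility

All randomness flows through explicit integer seeds; every generator
and every stochastic operation is byte-reproducible for a fixed seed,
and the pipeline writes a manifest of configuration, seed, and input
and output digests. The test suite exercises: classifier recovery on
200 planted proteins at identity 0.6 (requiring ≥ 95% agreement);
fold-detector specificity on 100 composition-matched random sequences
at Z = 6 with 200 shuffles (requiring ≥ 95 rejections); bootstrap
support ≥ 95% for the planted central split of two synthetic clades at
100 replicates; and exact recovery of additive distance matrices.
These sizes are chosen to give tight binomial evidence for the stated
rates while keeping the default test run fast.

# Known limitations

* Fold detection is pairwise-template based; remote homologs that a
  profile or HMM search would recover may be missed, and the Z
  threshold of 6 is calibrated to that stronger method's null, not
  re-derived for pairwise alignment.
* The signal-peptide and LRR detectors are deliberately simple
  heuristics; they are adequate for architecture flags, not substitutes
  for dedicated predictors.
* Multi-globin proteins are reported, not classified.
* Bayesian and maximum-likelihood tree inference are out of scope; the
  tree machinery is NJ-only, and clade-conservation claims are tested
  against generating trees on synthetic data.
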