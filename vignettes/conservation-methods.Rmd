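---
title: "Conservation scoring, clade bias, and homolog classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservation scoring, clade bias, and homolog classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alncons)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the parameters that matter, and the design
choices made where the design was genuinely open. The running example is
the molecular evolution of Oskar, a two-domain insect protein (an
N-terminal LOTUS domain and a C-terminal OSK domain joined by a variable
linker) whose conservation patterns across holometabolous and
hemimetabolous insects are of interest because only the former are known
to use it to nucleate germ plasm. Everything here applies to any protein
alignment with group structure.

## The homolog definition

A sequence is called a homolog when it carries a hit for the N-terminal
domain followed, after an interdomain region, by a hit for the C-terminal
domain, both with E-value strictly below 0.05. `classify_architecture()`
operationalizes this on HMMER per-domain hit tables (`domtblout` format,
envelope coordinates, per-domain independent E-values): per target it
selects the minimum-E-value hit of each domain and tests non-overlap
(`LOTUS end <= OSK start`), which encodes "followed by an interdomain
region" while allowing the degenerate zero-length linker. Rejections are
labelled `missing-domain`, `weak-evidence` (the cutoff is strict, so an
E-value of exactly 0.05 is rejected), `wrong-order`, or `overlap`. We use
the per-domain independent E-value rather than the full-sequence E-value
because the decision is made per domain.

Profile-HMM search itself is out of scope: hit tables are inputs, and the
iterative discovery loop (`iterate_discovery()`) delegates searching and
model rebuilding to a user-supplied backend function. The loop's contract
is convergence: it stops at the first iteration that adds no new homolog
id, records an audit trail of additions, and is guarded by a maximum
iteration count. The package's own tests drive it with scripted backends.

## Deduplication and duplication flagging

Transcriptome assemblies yield multiple near-identical sequences per
species (isoforms, fragmentary contigs); genuine within-species gene
duplications must not be collapsed with them. The package uses a single
identity threshold of 0.80 for both decisions:

* `deduplicate_taxon_group()` connects per-taxon sequence pairs with
  pairwise identity >= 0.80 into components and keeps only each
  component's lowest-E-value member (ties broken by id). Collapsing by
  connected component makes the operation idempotent and independent of
  input order.
* `flag_duplications()` then reports any taxon retaining two or more
  sequences whose pairwise identities are all < 0.80.

Pairwise identity is one minus the normalized Hamming distance computed
on the informative columns: columns gapped in both sequences are excluded
from the denominator, and a gap against a residue counts as a mismatch.
Counting both-gap columns would deflate identity for fragmentary
transcripts and collapse too little.

## Six-frame translation

`translate_six_frames()` reproduces the trim-and-clean conventions used
when screening assemblies: standard genetic code on the three forward
frames and the three frames of the reverse complement; codons containing
`N` translate to `X`; the incomplete trailing codon and trailing `X` runs
are trimmed; remaining stop codons are emitted as `X`. Trimming is
applied before stop-cleaning so that a sequence consisting only of a stop
codon still yields `X` rather than an empty string.

## The Valdar score

The central conservation statistic is a weighted sum of pairs. For
column $x$ with sequences $s_1, \dots, s_n$ and weights $w_i$:

$$V(x) = \frac{\sum_{i<j} w_i w_j \,\mathrm{Mut}(s_i(x), s_j(x))}
              {\sum_{i<j} w_i w_j}$$

$\mathrm{Mut}$ is a residue similarity in $[0,1]$ with
$\mathrm{Mut}(a,a) = 1$; the similarity of a gap, `X` or `*` against
anything is 0, which penalizes gappy columns and keeps $V \in [0,1]$.
The weights address a structural problem of public sequence data: a few
insect orders (Diptera, Hymenoptera) dominate the databases, and an
unweighted score would measure sampling density rather than evolutionary
constraint. We use evolutionary-distance weights
$w_i = \frac{1}{n-1}\sum_{j \ne i} d(i,j)$ with
$d(i,j) = 1 - \overline{\mathrm{Mut}}$ over the columns where both
sequences carry a residue ($d = 1$ when they share none); redundant
sequences get small weights. When all sequences are identical all
distances vanish and the weights fall back to uniform.

**Similarity matrix.** No specific matrix is mandated by the method, so
the default is BLOSUM62 (shipped with Biostrings) mapped per residue pair
by $\mathrm{sim}(a,b) = \frac{M(a,b) - \min M}{\min(M(a,a), M(b,b)) -
\min M}$, which is affine in $M(a,b)$, symmetric, exactly 1 on the
diagonal, and verified to lie in $[0,1]$ for BLOSUM62. The matrix is an
explicit argument of every function that uses it, so a different table
(e.g. one matching another implementation) can be swapped in without
touching the code.

## Jensen-Shannon divergence score

The JSD score measures, in bits, how far a column's amino-acid frequency
distribution $p$ is from a background $q$ (uniform by default):
$\mathrm{JSD}(p, q)$ with base-2 logarithms and mixture weight 1/2, which
is bounded by 1. Two adjustments follow the published divergence-score
method: the value is multiplied by the column's residue fraction, so
heavily gapped columns score low; and a window average blends each
column with its flanks, `final = 0.5 * own + 0.5 * mean(up to 3 columns
each side)`, reflecting that structurally important positions cluster in
sequence. Window size 3, weight 0.5 and base 2 are that method's
published defaults; the window weight set to 0 disables smoothing.

## Physico-chemical conservation tracks

**Electrostatic.** Each residue gets a charge: D, E $\to -1$; R, K
$\to +1$; H $\to +0.5$; everything else (including gaps and `X`) 0. The
column score is the charge sum divided by the **total** sequence count,
so gaps dilute toward 0; bounds are $[-1, 1]$, with $-1$ a negative
charge conserved across all sequences and $+1$ a conserved positive
charge. A fully histidine column scores exactly 0.5.

**Hydrophobicity.** Per column, the mean of a per-residue hydrophobicity
table over all sequences, gaps and `X` contributing 0; with the bundled
default table the score is bounded between $-2.20$ and $5.39$, and a
gap-free column of the most hydrophobic residue attains the maximum
5.39. The bundled default is the Kyte-Doolittle hydropathy index
affinely rescaled to exactly that range (isoleucine at 5.39, arginine at
$-2.20$); the scale is a pluggable argument, so any other published
20-residue table can be used, and only the declared bounds are treated
as fixed by the analysis design.

**RNA-binding and secondary structure.** Both aggregate per-sequence
tracks computed externally on the ungapped sequences (RNA-binding
propensity vectors; 3-state H/E/C secondary-structure strings). Tracks
are threaded through each sequence's gapped row; the per-column value is
the mean (RNA-binding) or the modal-state frequency (secondary
structure) over the sequences contributing a residue at that column.
Unlike the electrostatic/hydrophobic scores, the denominator here is the
*contributing* count, because a track is simply undefined at a gap — a
design asymmetry inherited from the electrostatic score's printed
definition, which explicitly divides by the total count. Columns with no
contributor carry `NA` and are excluded from region means. The
secondary-structure modal label breaks ties in the order H, E, C; the
score value is unaffected by tie-breaking.

## Conservation bias between clades

Comparing per-column conservation between a large clade and a small one
directly would confound conservation with sample size, because $V$ is
not invariant to $n$. The bias statistic therefore equalizes the sample
sizes by bootstrap: each of `n_iterations` (default 1,000) iterations
draws, without replacement, as many sequences from the large clade as
the small clade has, scores the sub-alignment (weights recomputed per
draw), and the per-column scores are averaged. The small clade is scored
directly. The bias is the ratio of logarithms,

$$\mathrm{bias}(x) = \frac{\log V_\mathrm{large}(x)}{\log V_\mathrm{small}(x)},$$

computed after clamping both scores into $[\varepsilon, 1-\varepsilon]$
with $\varepsilon = 10^{-6}$; the log base cancels in the ratio (natural
log is used). Clamping is needed because fully conserved columns reach
$V = 1$ exactly, where the ratio is $0/0$; the method's source
description does not address this case, so the clamp is this package's
choice, and it implies that columns essentially perfectly conserved in
the *denominator* clade saturate to very large bias values — region
means over such columns should be read with that in mind. Since scores
lie below 1, both logs are negative and the bias is positive, with
$\mathrm{bias} > 1$ meaning the numerator clade is *less* conserved at
that column. The statistic is exactly antisymmetric,
$\mathrm{bias}(a,b)\cdot\mathrm{bias}(b,a) = 1$, so the orientation is a
labelling convention; both orientations are available by swapping the
arguments of `conservation_bias()` or the group arguments of
`clade_bias()`.

Sampling is without replacement ("select N sequences" from a strictly
larger pool); with-replacement resampling is available behind the
`replace` flag. Fixing `seed` makes the whole bootstrap reproducible.

## Reference coordinates and regions

Score columns are reported against reference residue numbering (e.g.
*D. melanogaster* S457) via `map_reference()`, which maps residue $k$ of
the ungapped reference row to the alignment column holding it.
All column indices in this package are 1-based, matching R convention
and the 1-based residue numbering of structural biology; the exported
score table reports 1-based columns. Named regions (helices, sheets,
domains) are built from reference-residue intervals or explicit column
lists, and `region_mean()` averages a profile over a region, skipping
undefined columns.

## MCA of alignment sequence space

Each alignment column is a categorical variable with 21 levels (20 amino
acids + gap; `X` and `*` fold into the gap level). After removing
columns with occupancy below 0.3 (`filter_columns_by_occupancy()`, which
keeps columns at or above the cutoff, counts `X` as occupied, and is
idempotent and monotone in the threshold), the one-hot indicator matrix
is decomposed by standard correspondence analysis: relative frequencies
centered by row and column masses, scaled by the inverse square roots of
the masses, SVD, and projection of sequences onto the first three
principal coordinates. No Benzécri inertia correction is applied — the
reported inertia shares are the raw $\sigma_k^2 / \sum \sigma^2$ — since
the analysis is used for visual structure, not for inertia inference.
Eigenvector signs are arbitrary, so the first above-tolerance entry of
each dimension is made positive for reproducibility; when singular
values tie, the axes within a tied block are determined only up to
rotation, which is why the test suite compares rotation-invariant
quantities (coordinate Gram matrices and spectra) against its dense
eigensolver oracle. Symbols never observed in the data carry zero mass
and are dropped before scaling.

## The synthetic-data generator

`make_alignment()` draws star-phylogeny alignments: every sequence is an
independent draw, column by column, from a background distribution
(uniform over the 20 amino acids by default — the simplest null), except
at planted conserved columns where a group carries its planted residue
with probability $1 - p$ ($p$ the per-group substitution probability).
Gaps are inserted i.i.d. at a specified rate but never at conserved
columns unless requested, keeping planted truth labels exact.
`make_domain_hit_table()` plants the four architecture classes (correct,
reversed, single-domain, weak-evidence) with truth labels, and
`make_taxon_sequence_set()` plants per-taxon singletons, isoform pairs
(identity >= 0.8) and duplicate pairs (identity < 0.8) by mutating exact
numbers of positions, so realized identities sit deterministically on
the intended side of the threshold.

What the generator deliberately does **not** emulate: phylogenetic
correlation among sequences (no tree structure, so sequence weights are
near-uniform on synthetic data and their down-weighting behaviour is
exercised only qualitatively), indel structure (gaps are i.i.d., not
affine), and compositional biases of real proteomes. Passing tests on
synthetic data therefore validate the *computations*, not the biological
calibration of thresholds like the 0.80 identity cutoff.

## Numerical choices and degenerate inputs

* Valdar denominators use pair-weight sums; the degenerate all-zero
  weight case falls back to uniform weights rather than failing.
* All profile values are clipped to their declared bounds to absorb
  floating-point drift at the boundaries (e.g. $V$ of a fully conserved
  column is exactly 1 only up to rounding).
* The JSD uses $0 \log 0 = 0$ and requires a strictly positive
  background so the divergence is finite.
* Identity comparisons with no informative columns (both sequences all
  gaps) return `NA` rather than an arbitrary identity.
* `classify_architecture()` orders its rejection tests missing-domain,
  then weak-evidence, then geometry, so each target gets one
  well-defined reason.
* MCA requests beyond the available rank are truncated with a warning;
  an alignment with no variation returns all-zero coordinates and zero
  inertia.

## Problem sizes in the test suite

The suite validates the Valdar implementation against a brute-force
weighted sum-of-pairs oracle on alignments up to 8 sequences x 50
columns, checks score bounds on 1,000 randomized small alignments,
verifies the bootstrap against exhaustive enumeration of all
6-choose-3 sub-alignments, and demonstrates recovery of planted
clade-specific conservation by the region-mean bias on 20 seeds of
30 + 30 sequences x 35 columns. These sizes were chosen as the smallest
that exercise every code path with meaningful statistical structure;
all scoring functions scale to realistic alignments (hundreds of
sequences, thousands of columns) since the per-column cost is a single
weighted matrix contraction.

## Known limitations

* The bias statistic's clamping makes it unstable exactly where the
  denominator clade is perfectly conserved; comparisons of region means
  should check for saturated columns.
* The bundled hydrophobicity table preserves the analysis's documented
  bounds but is a rescaled standard hydropathy index; analyses that
  depend on a specific published table should pass it explicitly.
* Deduplication assumes the per-taxon sequences are already aligned to
  each other; it does not run an aligner.
* The discovery loop's correctness depends on the supplied backend being
  deterministic; a stochastic backend can prevent convergence.
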