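---
title: "Detecting clade-specific functional divergence in protein families"
author: "fdscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting clade-specific functional divergence in protein families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdscan)
```

## The problem

When a protein lineage acquires a new function, the change typically
leaves a sequence signature: a position that is conserved across the rest
of the family fixes a biochemically radical replacement in one clade and
is then conserved again in its new state.  `fdscan` scans families of
homologous proteins for exactly this signature, one gene tree at a time,
so that horizontal gene transfer — which makes different genes disagree
about the species phylogeny — does not confound the analysis.  Aggregated
over many families, the branch-level calls describe which species, and
which functional categories of genes, experience more or less functional
change than the proteome-wide background.

## The statistic

For every internal node of a rooted gene tree whose two descendant
clades each hold at least 4 sequences and which leaves at least one
outgroup sequence, each alignment column is scored as

FD = |x&#772;₁ − x&#772;₂| / SE,&emsp;SE = √(s₁²/n₁ + s₂²/n₂),

where x&#772;₁ is the mean BLOSUM62 substitution score over all non-gap
(clade-1 member, outgroup member) pairs at that column, s₁² the sample
variance of those pair scores and n₁ the number of pairs (likewise for
clade 2).  Large scores flag columns where one clade's residues are
systematically more radical with respect to the outgroup than the other
clade's.  Two numerical conventions matter:

* if x&#772;₁ = x&#772;₂ the score is 0 regardless of SE;
* otherwise SE is floored at 10⁻⁶, so a column that is perfectly
  conserved within each partition class but differs between them gets a
  very large, finite score and remains rankable.  Because the same
  convention applies to the simulated null columns, such "clean
  bifurcation" columns compete against their own kind in the null and
  calibrate to honest p-values.

A column is not scorable (and is excluded) when either clade or the
outgroup contributes no non-gap pair.  Variance uses the n−1 denominator
and is 0 when a class has one pair.

## Significance

The distribution of FD under neutrality depends on the tree, so the null
is calibrated per node by simulation: gap-free alignments are evolved on
the group's own tree (topology and branch lengths) under the JTT model
with 4-category discrete-gamma rate heterogeneity (shape α = 1.0,
mean-of-quartile category rates), the simulated length being the real
alignment length minus the mean per-sequence gap count (rounded
half-to-even).  Every simulated column is scored at the same partition
and the scores are pooled.  At least 1000 replicate alignments are drawn;
thereafter replication continues in batches of 100 until the running mean
and standard deviation of the pooled scores both move by less than 10⁻⁶
between batches, with a hard cap of 10 000 replicates and a warning
(class `fdscan_unconverged`) when the cap is reached first.  In practice
the pooled moments move by ~10⁻⁴ per batch at these sizes, so
calibrations typically run to the cap; the cap, not the tolerance, is the
effective replicate count.

Observed sites receive add-one empirical upper-tail p-values,
p = (1 + #{null ≥ observed}) / (1 + n_null), which are corrected per node
by Benjamini–Hochberg at α = 0.05.  A branch is called functionally
divergent when at least one of its sites stays significant.  Both the
pooling (per node, across replicates and columns) and the correction
family (per node) are package choices; the alternatives (per-node maxima,
per-gene or global correction) are deliberately not implemented so that
there is exactly one calibrated mode.

## Trees

Gene trees are built per group from maximum-likelihood pairwise distances
under JTT + Γ₄ (gap columns excluded pairwise; estimates above 10
substitutions/site are treated as saturated and clamped) with BIONJ, and
midpoint-rooted.  Midpoint rooting was chosen because the method needs a
root only to orient clades against outgroups, and no outgroup information
beyond the alignment itself is assumed.  Negative BIONJ branch estimates
are clamped to zero.  The root node itself is never testable (its
outgroup is empty), which is why a group needs at least 9 sequences: two
clades of 4 plus one outgroup sequence.

## Group filtering

Groups enter the scan only when they have ≥ 9 sequences, all sequences
carry one and the same single-letter functional tag, and the tag is not
one of the poorly characterised catch-all categories R or S.  Ambiguity
letters (B, Z, X, U, O, J as a residue) are rejected by default because
their BLOSUM62 scores are ill-defined for the statistic; a permissive
mode converts them to gaps instead.

## Enrichment and clustering

Each tested branch carries its group's category tag and is attributed to
every species with a sequence in either clade (outgroup members are not
attributed; the attribution rule is a package construction).  For a unit
(a category, a species, or a category-within-species cell) with o
FD-positive branches out of t attributed tests, a 2×2 Yates-corrected
chi-squared test compares the unit against all other tests, falling back
to Fisher's exact test when any expected cell is below 5.  The unit is
*enriched* when p < 0.05 and o exceeds its margin expectation,
*impoverished* when p < 0.05 with a deficit, *neither* otherwise, and
*no-data* with zero attributed tests.  No correction is applied across
units, mirroring common practice for these category-level screens.
Lifestyle associations use the same machinery on 2×3 status tables
(exact enumeration up to a table total of 1000, Monte-Carlo beyond).

The species × category status grid (+1 / 0 / −1 / missing) is clustered
in two dimensions by Euclidean distance with complete linkage (the
linkage is configurable; only the distance is dictated by the method).
Missing cells are imputed as 0 for distance purposes only and flagged.
Labels are sorted before clustering so the dendrograms do not depend on
input order.

## The synthetic-data generator

All validation runs on synthetic data with known ground truth, because
the statistical claims of the method are about its operating
characteristics, not about any particular proteome.

**Neutral groups** (`make_neutral_group`) evolve a gap-free alignment
(default 16 taxa × 300 columns) under JTT + Γ₄ on a random Yule-shaped
tree with i.i.d. exponential branch lengths (mean 0.1
substitutions/site — a typical within-family divergence for bacterial
protein alignments).  About half of such random 16-taxon trees contain no
testable node at all (two clades of ≥ 4 with an outgroup are not
guaranteed); neutral error rates are therefore averaged over the
alignments that have at least one tested node.

**Divergent groups** (`make_divergent_group`) use a fixed "signature"
topology — two balanced clades of 4 on stems of 0.12, an outgroup cherry
(tip branches 0.10–0.18) on a 0.45 stem, within-clade branch lengths
uniform on 0.5–1.2 × 0.1 — chosen so that (i) distance-based
reconstruction recovers the tested node essentially always at 300
columns, (ii) midpoint rooting falls on the outgroup stem (clade depth
stays well below the stem length, with margin for the branch-length
inflation the planted sites cause), and (iii) neutral clade-wide
substitutions, the background the planted signal competes with, stay
rare.  Bounded uniform rather than exponential within-clade lengths are
deliberate: heavy-tailed draws occasionally produce a clade deeper than
the outgroup stem, which silently re-roots the tree inside the clade and
destroys the tested node — a property of the positive control, not of
the method.  Planting then selects the k most conserved columns outside
the target clade, ranked by the radicality their consensus residue
admits (its BLOSUM62 diagonal minus the most negative entry against it),
and replaces the target clade's residues with that most-radical residue.
This is the conserved-then-radical signature the statistic targets;
rate-inflation planting was rejected because it gives no unambiguous
per-site ground truth.

**Datasets** (`make_dataset`) combine divergent groups (planted in the
clade of one focal species; background species rotate so that none is
attributed to more than one planted branch) with neutral groups across
categories, writing FASTA/TSV inputs plus a truth JSON.

What the generator does *not* emulate: indels (simulated alignments are
gap-free; real gaps only shorten the simulated length), alignment error,
among-site compositional heterogeneity, and HGT beyond
independent-random gene trees.  Passing the synthetic checks therefore
demonstrates calibration and recovery under the model's own assumptions,
not robustness to misalignment or model violation.

## Problem sizes and reproducibility

The shipped validation uses 20 neutral alignments (16 × 300), 20
divergent-group seeds and 10 dataset seeds — sizes at which the empirical
false-positive rate, planted-site ranking and enrichment recovery are
stable.  All randomness flows from user-supplied seeds; per-group and
per-node streams are derived by hashing the master seed with the unit
identifier (`derive_seed`), so results are identical regardless of the
order in which groups are processed.  The compiled null-calibration
kernel draws from R's RNG, so `set.seed()` governs it too.

## Known limitations

* The SE floor makes fully conserved contrasts compete purely on the
  magnitude of the mean difference; two radical clean bifurcations of
  equal magnitude are indistinguishable in rank.
* Calibrations essentially always run to the replicate cap (see above);
  the convergence tolerance is retained for compatibility with the
  method's description but is not expected to trigger at these problem
  sizes.
* Midpoint rooting can place the root inside a genuinely deep clade, in
  which case that clade's node is not testable on that tree.
* Branch-to-species attribution treats every clade member equally; a
  species deep inside a large clade is attributed a divergence event that
  may have occurred on a stem it shares with many others.
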