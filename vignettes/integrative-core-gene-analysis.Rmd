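---
title: "Integrative nomination of core genes and a master-regulator miRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative nomination of core genes and a master-regulator miRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coremir)
```

## The analysis in one paragraph

Aggressive tumors accumulate coherent lesions across molecular layers: a
driver gene tends to be *both* differentially expressed and copy-number
altered in the concordant direction, and its expression change is often
reinforced by an oppositely deregulated miRNA.  `coremir` implements that
integration chain for two-class (tumor vs normal) count-based cohorts.  It
(i) calls differentially expressed genes and miRNAs with an exact
negative-binomial test under balanced resampling, (ii) calls amplified and
deleted genes from segmented copy-number profiles with a simplified
GISTIC-style score and permutation q-values, (iii) reduces a multi-database
miRNA-target table to consensus target sets by vote counting, (iv)
intersects the three layers with direction logic to nominate **core genes**
(up + amplified + target of a down-miRNA, or down + deleted + target of an
up-miRNA), (v) intersects the core set with published signatures, (vi)
tests every deregulated miRNA for Fisher-exact over-representation of its
targets in a gene co-expression network to nominate a **master-regulator
miRNA**, and (vii) scores every candidate feature set by cross-validated
random-forest AUC.

## Differential expression: the exact NB test

Counts for feature $g$ in sample $j$ of class $c$ are modeled as
$y_{gj} \sim \mathrm{NB}(\mu_{gc}, \phi)$ with variance
$\mu + \phi\mu^2$ and a single common dispersion $\phi$.  After rescaling
every sample to the geometric mean of the library sizes (integer
pseudo-counts), $\phi$ is estimated by maximizing the conditional
log-likelihood given each class's total, summed over features — the
single-factor qCML construction.  The maximizer is located on a log-spaced
grid over $[10^{-6}, 10]$ and refined by golden-section search; the grid
value wins if refinement cannot beat it, so a boundary solution (no
overdispersion evidence) is returned honestly.

For each feature the two-group test conditions on the total count $t$: the
class-1 sum $A$ is then distributed as a sum of $n_1$ i.i.d. NB variables
given $A + B = t$.  Because a sum of $n$ i.i.d. $\mathrm{NB}(\mu, \phi)$
variables is NB with size $n/\phi$ and mean $n\mu$, the conditional law is
evaluated exactly on $0..t$, and the two-sided p-value adds the probability
of every outcome no more likely than the observed one (ties compared at
relative tolerance $10^{-12}$ so the rule is platform-stable).  At
$\phi = 0$ the Poisson limit gives a binomial conditional law.  The test is
validated in the suite against brute-force convolution of the per-sample
pmfs, which never shares code with the implementation.

Features are called up (down) at $|\log_2 \mathrm{FC}| > 1$ and
Benjamini–Hochberg FDR $< 0.01$.  Fold changes use class means of the
pseudo-counts with a 0.5 prior count per class, so all-zero classes stay
finite.  To neutralize class imbalance, calling is repeated over balanced
resamples (all minority samples plus an equal-size draw of the majority;
seven resamples by default) and a feature must pass in **every** resample —
the conservative reading; union and majority combination are available via
`analysis_config(resample_combine =)`.

## Copy-number calling

Segmented profiles (SEG, 1-based inclusive on disk, 0-based half-open in
memory) are first cleaned: segments with fewer than four markers are
iteratively absorbed into the same-chromosome neighbor closest in segment
mean (marker-weighted update, left-neighbor tie-break); marker totals are
conserved.  Per gene and sample, the amplitude is the marker-weighted mean
log2 ratio over the gene span (any base-pair overlap counts).  The
amplification score is
$g_{\mathrm{amp}} = \tfrac1S \sum_{s:\ a_{gs} > 0.1} a_{gs}$ —
frequency × amplitude, the G-score construction — and the deletion score
mirrors it below $-0.1$.

Significance comes from a within-sample circular-shift null: each sample's
gene-ordered amplitude vector is rotated by a uniform offset, preserving the
sample's amplitude distribution and local autocorrelation; scores are
recomputed and pooled across genes and permutations, giving
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\}) / (1 + n_{\mathrm{null}})$,
then BH over genes.  A gene is amplified when $q < 0.25$ and its score is
positive (deleted mirrored); a gene significant in both directions is set
neutral with a warning.  Gene-level calling (rather than marker-level peak
peel-off) is deliberate: genes are the unit every downstream intersection
consumes.

## Consensus targets, integration, and the master regulator

A miRNA–gene pair is a consensus target when predicted by at least five of
the ten databases (distinct database names only; unknown names still vote,
with a log message, since database universes drift between versions).  The
integration is then pure, direction-aware set algebra, with the invariant
chain *core ⊆ expression∩CNA ⊆ DE* checked on every run.  Core-gene records
list exactly the direction-opposed regulating miRNAs; a miRNA appearing in
both direction sets aborts the run as a validation error.  Gene identity is
case-folded symbol matching without alias resolution.

Master-regulator nomination tests each deregulated miRNA's consensus
targets for over-representation among the network genes with the one-sided
hypergeometric tail $\Pr(X \ge k)$, $X \sim \mathrm{HG}(N, K, n)$.  The
background $N$ is every gene carrying at least one consensus annotation
plus the network genes — the study never defines its universe, so the
choice is explicit and configurable.  Raw $p < 0.05$ defines enrichment (no
multiple-testing correction, matching the published rule; BH is available
but off by default).  Candidates are ranked by ascending $p$, ties by
descending target count, then lexically.

## Classification

Feature sets are evaluated on $\log_2(\mathrm{count}+1)$ values with a
random forest (500 trees, default $\sqrt{p}$ feature subsampling — the
defaults of the R package the approach is built on), stratified 10-fold
cross-validation, out-of-fold class-probability scores pooled per resample,
and AUC computed by the rank statistic with 0.5 credit for ties.  Pooling
out-of-fold scores (rather than averaging per-fold AUCs) is a deliberate
choice: at ~50 samples per class, per-fold AUCs rest on 5-sample strata and
are unstable.  The same balanced-resampling engine as the DE stage supplies
the evaluation cohorts, and the report carries one AUC per resample plus
their mean.  The random-gene baseline draws matched-size feature subsets
uniformly without replacement and evaluates them identically.

## The synthetic cohort

Because the original cohorts live behind external accessions, the package
ships a generator whose defaults are the validation conditions used
throughout the tests: 40 tumor vs 40 normal samples; 3000 genes and 150
miRNAs with log-uniform baseline means in 20–200 counts; NB dispersion
$\phi = 0.1$; planted features at a symmetric $\log_2$ fold change of 2;
copy-number amplitude 0.8 log2 units carried by 80% of tumor samples;
target tables voting 7 databases for true pairs vs 2 for noise pairs; 20
core genes (10 per direction) plus 4 decoy genes per direction in every
single- and double-layer Venn region; 24 deregulated miRNAs including one
master regulator targeting 4 of the 19 network genes.  Planted baseline
means are drawn from the upper range (80–200) so a real expression filter
would retain them — the filter is applied, not bypassed.  The cohort size
(3000 genes, ~2% of them planted) keeps the planted fraction at
transcriptome-like rarity, which is what makes the random-gene baseline
comparison meaningful: random matched-size draws are then dominated by null
features, as in real data.  Two miRNA loci are planted inside altered
regions so the locus-level miRNA/CNA concordance check has positive and
negative cases.

What the generator does **not** emulate: real library-size variation is off
by default (a `lib_size_factors` knob exists and the equalization step has
its own tests); no gene-gene correlation, GC or length effects; planted
segments carry their amplitude exactly (no per-sample amplitude noise), so
segment-level variance is optimistic; symbols and coordinates are synthetic.
Passing recovery tests therefore demonstrates the *logic* of the chain —
direction rules, thresholds, rankings — not performance on real tumor data.

## Numerical choices and degenerate inputs

* Quantile filter: threshold is the linear-interpolation quantile (R type 7)
  of feature means; retention is strictly greater.  All-equal means filter
  everything, with a warning.
* `exact_nb_test` returns $p = 1$ for an all-zero feature (total $t = 0$).
* Dispersion search space $[10^{-6}, 10]$; all-zero features are excluded
  from the likelihood.
* Permutation q-values refuse to run below 20 permutations (unstable null).
* Segment merging on a chromosome whose marker total is below the threshold
  collapses to a single segment with a warning.
* Every stochastic step (generator, resampling, permutations, folds, random
  forests, baseline draws) is driven by explicit integer seeds; two runs at
  the same seed produce byte-identical reports.

## Problem sizes used in the shipped analyses

The analysis drivers and the acceptance script run the default design above
(3000 × 80 cohort, 200 copy-number permutations, 7 × 10-fold CV, 11
baseline draws); the unit-test suite exercises the same code paths on
300-gene cohorts with 3 resamples, 5 folds, 100 trees and 50 permutations.
These sizes are the package's validation conditions, chosen so the whole
chain — including the exact convolution tests and exhaustive oracles — runs
comfortably on a laptop.

## Known limitations

Common (not tagwise) dispersion; no TMM or GLM designs; gene-level CNA
without focal/broad decomposition or peel-off; symbol-string gene identity;
the enrichment universe is a modeling choice the original study leaves
unspecified; and the classifier is a fixed-hyperparameter random forest —
the goal is comparable evaluation across feature sets, not maximal AUC.
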