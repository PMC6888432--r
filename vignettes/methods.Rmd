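---
title: "Methods: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, the conventions that had to be fixed where the underlying
methods literature leaves them open, the synthetic-data generator's
assumptions, and the limits of what the tests demonstrate.

## The site-rate model

Evolutionary rates per site are estimated by the empirical Bayes approach
popularized by Rate4Site-style tools. The data are one alignment column at
a time; the tree and its branch lengths are taken as given and never
re-optimized. The substitution process is the JTT amino-acid replacement
model: the published exchangeability matrix $S$ and stationary frequencies
$\pi$ are packaged constants, combined as $Q = S\,\mathrm{diag}(\pi)$ and
normalized so that $-\sum_i \pi_i Q_{ii} = 1$, i.e. branch lengths are in
expected substitutions per site. A `jtt+f` mode replaces $\pi$ with
frequencies observed in the alignment (with a $10^{-10}$ pseudocount
against absent residues); the default is plain JTT, the usual choice for
rate estimation even when tree inference used `+F`.

Among-site rate variation has a discrete-gamma prior: a
$\Gamma(\alpha,\alpha)$ law (mean 1) cut into $K = 16$ equal-probability
bins, each represented by its **bin mean** so that the category rates
average exactly 1 (a bin-median discretization would not). $K = 16$ is the
default throughout. The per-column likelihood $L_c(r)$ is computed by
Felsenstein pruning with $P(t r) = e^{Q t r}$ via the eigendecomposition of
the symmetrized rate matrix
$\mathrm{diag}(\sqrt\pi)\,Q\,\mathrm{diag}(1/\sqrt\pi)$, computed once per
(branch, rate) pair. Gap and `X` characters are missing data: their leaves
carry all-ones partial vectors, so they neither support nor penalize any
rate. Columns are rescaled by their running maximum at every interior node
(log-space accumulation), which keeps likelihoods representable for
hundreds of taxa; the unscaled path is exact, so the zero-rate likelihood
of a constant column is *identically* $\pi_a$, with no rounding through
`exp(log(.))`.

The shape $\alpha$ is fitted by maximizing the marginal log-likelihood
$\sum_c \log \frac1K \sum_k L_c(r_k)$ with a bracketed scalar search on
$[0.02, 20]$. The optimizer's interior estimate is compared against both
bracket endpoints and the best of the three is returned; data with no rate
signal (e.g. a fully invariant alignment) pin $\alpha$ to a boundary and a
warning is emitted. The posterior mean
$\hat r_c = \sum_k r_k L_c(r_k) / \sum_k L_c(r_k)$ uses uniform category
weights, as the discrete-gamma construction implies. Columns in which
*every* taxon is gap/`X` are flagged `no_data`, assigned the prior mean
(≈ 1), and excluded from standardization.

Z scores use the **population** standard deviation (divisor $n$) over
non-flagged columns; standardization of a constant vector is an error
rather than a silent zero. Z < 0 means slower than the protein's average;
this sign convention drives the slow/fast split downstream.

Unrooted input trees with a basal trifurcation are accepted as-is: under a
reversible model the likelihood is invariant to root placement (verified
by a re-rooting test), so no rerooting is needed.

## Disorder, phosphosites, variants

Disorder scores are IUPred-style per-residue values in $[0,1]$ with 0.5 as
the order/disorder divide. The boundary is counted as **disordered**
(score ≥ 0.5): the cutoff convention had to be fixed one way and is a
configurable argument. The per-column consensus is disordered when at
least 50% of the non-gap cells are disordered (inclusive at exactly 50%,
mirroring the phosphosite majority rule for internal consistency); the
heat-map matrix rows follow the ladderized tree order, which is
deterministic for a fixed input tree. For reference-coordinate residue
classifications the default uses the reference taxon's own track
(`reference_only`), matching per-protein rate-vs-disorder overlays; a
`consensus` mode is available. The slow/fast split is at Z = 0 exactly,
with Z = 0 counted as fast (slow is *strictly* negative, i.e. strictly
below the protein average).

Phosphosite calls require both a propensity ≥ 0.75 (inclusive) and an
S/T/Y residue — a propensity track can only mark a phospho-acceptor. A
column is a conserved site when positives reach 50% of **all sequences in
the alignment**: gapped sequences count in the denominator (they are part
of "the amount of sequence"), and an alternative non-gap denominator is a
config option. The reference-coordinate report by default intersects
conserved columns with reference-positive calls ("conserved human
sites"); both the raw and intersected flags are returned.

Variant context reports the nearest conserved-phosphosite distance as a
raw residue count (0 = overlap) without imposing a closeness threshold,
and domain intervals always come from user configuration — no authoritative
boundaries ship with the package. Distribution summaries are reported both
site-weighted and case-weighted because recurrent mutations otherwise
dominate.

## Profiling and clustering

Presence/absence profiles use a Smith–Waterman score threshold of 150 when
scores (rather than member flags) are supplied. Ward clustering is
implemented with the Lance–Williams update applied to the Manhattan
distances **as provided** (the `ward.D` convention). "Ward's method" on a
non-Euclidean dissimilarity is genuinely ambiguous, so the squared-update
variant (`ward.D2`-style) is available behind a flag; the plain variant is
the default because it operates on the stated distances directly. Ties —
common on binary data, where distances are integers — are broken by the
lexicographically smallest pair of smallest-original-row indices, making
the merge sequence fully deterministic. The flat cut at $k = 4$ uses the
standard tree-cutting algorithm, and cluster ids are renumbered by first
appearance in row order for reproducibility.

Class labels operationalize "conserved to depth X": for each cluster and
each nested taxonomy group, compute mean presence inside the group and in
its complement; the label is the **broadest** group with inside-presence
≥ 0.5 and outside-presence < 0.25, else `unresolved`. Both thresholds are
arguments. With the canonical nesting
(chordates ⊂ metazoans ⊂ multicellular ⊂ eukaryotes) this yields the
Class 1–4 naming. The defaults assume each group is more than twice the
size of the one it contains, so a clade-restricted cluster cannot
accidentally qualify at the next broader depth; users with very different
group sizes should revisit `insideMin`.

## Tissue specificity

Per protein over $n$ tissues: $\mu = \frac1n\sum x_i$,
$s = \sqrt{\frac1n\sum (x_i - \mu)^2}$ — the population SD, divisor $n$,
deliberately not the sample SD, which would widen every threshold — and
tissue $i$ is specific when $x_i > \mu + 1.65\,s$, a strict inequality, so
a zero-variance protein is never specific. 1.65 is the one-sided 90%
confidence factor. TPM values are used untransformed; a log-transform is
left to the caller since the statistic is meant to run on the atlas-style
TPM scale.

## The synthetic-data generator

The generator emulates each input at a reference scale chosen once:

* **Tree**: Yule topology (uniform random tip splitting), 24 taxa,
  exponential branch lengths with mean 0.1 substitutions/site — a total
  tree length around 4–5, typical of a chordate ortholog family, deep
  enough to carry rate signal without saturating.
* **Alignment**: 300 sites under JTT; per-site rates drawn from the
  $K = 16$ discretization of a shape-0.5 gamma (strong heterogeneity, as
  empirical shape estimates for disordered proteins tend to be low).
  Disordered blocks (alternating 50-residue blocks by default) get a 3×
  rate multiplier, encoding the faster evolution of flexible disorder.
* **Disorder tracks**: Beta(2, 8) scores in ordered regimes and Beta(8, 2)
  in disordered ones (means 0.2/0.8) — distributions that straddle the 0.5
  cutoff cleanly so per-taxon noise, not the generator, is the obstacle.
* **Phosphosites**: each planted reference position is made positive
  (serine, score in U(0.75, 1)) in an independent Binomial(n, f) subset of
  taxa, f = 0.7 by default; baseline scores are U(0, 0.5).
* **Profiles**: four classes × 15 proteins over 95 species in nested
  groups of 8/20/45/95, class pattern = presence in exactly one group,
  5% i.i.d. cell flips.
* **Expression**: 200 proteins × 37 tissues, log-normal(1, 1) baseline,
  spiked cells ×50.
* **Variants**: positions drawn with weight ρ = 4 inside domain intervals
  (which the bundle places on the ordered blocks), reference amino acid
  from the reference row, 1 + Poisson(1) cases, 80% labeled pathogenic.

One bundle seed expands into fixed per-stage substreams, so each stage is
independently reproducible. Alignments are generated gap-free by default
(a gap-masking option exists for gap-handling tests): real indel processes,
alignment error, phylogenetic autocorrelation of disorder scores, and
kinase-specific phosphosite structure are *not* modeled. Passing tests
therefore demonstrate correctness of the computations and recoverability
under the stated generative model — not robustness to misalignment or
predictor bias on real data.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at the reference scale
above (24 taxa × 300 sites for recovery, 200 sites for the
ordered/disordered contrast, five seeds with medians reported; 40–100
random instances for the enumeration and clustering oracles; 10⁴ × 37 for
the specificity null). Scalar optimization tolerance is 1e-4 on α;
likelihood comparisons against the enumeration oracle hold to a relative
1e-10; Z standardization holds to 1e-9. Exact Mann–Whitney enumeration is
used when both groups have ≤ 8 values (beyond that the tie-corrected
normal approximation takes over, without continuity correction so it
matches the classical large-sample form).

## Known limitations

* Branch lengths are never re-estimated; a misscaled input tree biases
  α and compresses Z contrast (rank order is more robust).
* The empirical-Bayes posterior mean shrinks extreme sites toward 1;
  Z scores are comparable within a protein, not across proteins.
* The four-cluster cut is taken as given; no model selection on k.
* The class-labeling thresholds (0.5 inside / 0.25 outside) are a
  pragmatic operationalization of "conserved in clade X", not an inferred
  quantity.
* The specificity statistic ignores TPM uncertainty and tissue
  correlation; it is a screening rule, not a test with calibrated error.
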