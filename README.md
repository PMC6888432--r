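# evoscape

Integrative molecular-evolution analysis of protein families with extensive
intrinsically disordered regions (IDRs) — the kind of dataset built around
neurodevelopmental disease proteins such as MeCP2, CDKL5 and FOXG1 and their
chordate orthologs. The package is aimed at molecular evolution and
structural bioinformatics researchers who have an alignment, a tree and
per-residue predictor tracks in hand and want the downstream integration:
evolutionary rates per site, order/disorder context, conserved
phosphosites, pathogenic-variant context, evolutionary classes of
interaction partners, and tissue-specific expression.

## What it computes

**Per-site evolutionary rates (empirical Bayes).** For alignment column
`c`, a fixed tree with branch lengths `t`, and the JTT amino-acid
replacement model with rate matrix `Q` (normalized to one expected
substitution per site), the rate multiplier `r` has a discrete-gamma prior:
`K = 16` equal-probability categories of a Gamma(α, α) law (mean 1), each
represented by its bin mean `r_k`. The posterior-mean rate of the column is

    r̂_c = Σ_k r_k L_c(r_k) / Σ_k L_c(r_k)

where `L_c(r)` is the Felsenstein pruning likelihood with transition
probabilities `P(t r) = exp(Q t r)`; gaps and `X` are missing data
(all-ones partial vectors). The shape α is estimated by maximizing the
marginal likelihood `Σ_c log[(1/K) Σ_k L_c(r_k)]`. Rates are standardized
as Z scores (population SD) — `Z > 0` marks faster-than-average evolution —
and projected onto the reference (human) sequence coordinates.

**Disorder integration.** Per-residue disorder scores (IUPred-style, 0–1)
are spread over the alignment in ladderized tree order (heat-map matrix);
residues are disordered at score ≥ 0.5; disordered residues split into
*constrained disorder* (`Z < 0`) and *flexible disorder* (`Z ≥ 0`); the
ordered-vs-disordered rate distributions are compared with a two-sided
Mann–Whitney U test.

**Conserved phosphosites.** NetPhos-style scores call a site at ≥ 0.75 on
S/T/Y residues; a column is conserved when ≥ 50% of *all* sequences in the
alignment (gaps count in the denominator) are positive.

**Variant context.** Pathogenic missense variants are joined to domain
intervals, structure/evolution categories and the distance to the nearest
conserved phosphosite, then summarized over
(domain × order × slow/fast) cells, site- and case-weighted.

**Phylogenetic profiling.** Binary ortholog presence/absence profiles
(presence at Smith–Waterman score ≥ 150 when scores are given) are
clustered on Manhattan distance with Ward's method and cut into four
clusters; each cluster is labeled by its taxonomic conservation depth
(chordate / metazoan / multicellular / eukaryote classes).

**Tissue specificity.** Per protein over `n` tissues with TPM values `x_i`:
`μ = mean`, `s = population SD`; tissue `i` is specific when
`x_i > μ + 1.65 s` (the 90% confidence bound).

Every input can also be *simulated* with known ground truth
(`simulateBundle()` and the `simulate*` family), so the full pipeline runs
and is testable without any external database.

## Worked example

```r
library(evoscape)

## synthetic bundle: 24 taxa, 300 sites, gamma shape 0.5, disordered blocks
## evolving at 3x the ordered rate, planted phosphosites and profile classes
paths <- simulateBundle("demo_in", seed = 1)
res <- runPipeline(list(
  alignment = paths$alignment, tree = paths$tree,
  disorder = paths$disorder, phospho = paths$phospho,
  domains = paths$domains, variants = paths$variants,
  orthologs = paths$orthologs, taxonomy = paths$taxonomy,
  expression = paths$expression,
  referenceId = "s01", outDir = "demo_out"))
str(res$summary[c("alpha", "mann_whitney", "n_conserved_ptm",
                  "class_sizes")], max.level = 2)
```

Output (exactly as printed by the code above):

```
List of 4
 $ alpha          : num 0.381
 $ mann_whitney   :List of 7
  ..$ U               : num 14522
  ..$ p               : num 1.32e-05
  ..$ method          : chr "normal approximation (tie-corrected)"
  ..$ medianDisordered: num -0.137
  ..$ medianOrdered   : num -0.589
  ..$ nDisordered     : int 151
  ..$ nOrdered        : int 149
 $ n_conserved_ptm: int 4
 $ class_sizes    :List of 4
  ..$ Class1_chordate     : int 15
  ..$ Class2_metazoan     : int 15
  ..$ Class3_multicellular: int 15
  ..$ Class4_eukaryote    : int 15
```

Reading it: the fitted gamma shape (0.38) reflects strong among-site rate
heterogeneity (the generator mixes a 0.5-shape prior with 3× disordered
blocks, which the single-gamma fit absorbs as a lower shape); the
Mann–Whitney p ≈ 1.3e-05 with median Z higher in disordered residues
reproduces the expected ordered-vs-disordered rate separation; 4 of the 10
planted phosphosites (conserved in 70% of taxa on average) pass the strict
report that also requires the reference sequence itself to be positive;
the four planted 15-protein profile classes are recovered exactly with
their depth labels.

A thin CLI wrapper with `simulate` and `run` subcommands is at
`inst/scripts/evoscape.R`.

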