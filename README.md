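# evnetprop

Network propagation of exercise-responsive extracellular-vesicle (EV) miRNA
signals, from raw counts to a probability of a cartilage-aging phenotype.

Acute exercise changes the miRNA cargo of circulating EVs; those miRNAs
repress target genes in recipient tissues such as articular cartilage.
`evnetprop` is for computational biologists who want to quantify the
downstream, tissue-specific impact of such a miRNA shift. It implements the
full inference chain as composable, pipe-friendly R functions:

1. **Paired differential expression** of a miRNA × sample count table:
   low-count filtering (the `filterByExpr` rule), TMM/CPM normalization,
   and an empirical-Bayes moderated paired *t* on per-subject post − pre
   log-CPM differences, calling miRNAs at |log₂FC| > 1, p < 0.05 (BH
   q-values reported).
2. **Cross-database target seeding**: per DE miRNA, the intersection of two
   target databases, keeping strong experimental evidence; the deduplicated
   union is the seed gene set.
3. **Random walk with restart** on a weighted tissue-specific functional
   gene network: for each seed, iterate `p ← (1 − r) W p + r e` on the
   column-stochastic operator `W` (restart probability `r = 0.7`) to a
   stationary affinity vector; an exact linear-solve mode
   `p = r (I − (1 − r) W)⁻¹ e` is built in as an oracle. Per seed, the
   pseudo-activated set (affinity > threshold) and the top-k vicinity
   (k = 20, lexicographic tie-breaks) are derived.
4. **Pathway over-representation**: one-sided hypergeometric tests of the
   propagated gene sets against a GMT collection (universe = network
   nodes), BH FDR, plus per-pathway *perturbation counts* (how many seed
   runs hit each pathway).
5. **Hallmark association**: logistic regression (IRLS with step-halving
   and separation detection) of binary aging-hallmark labels on
   perturbation counts, reporting `P(aged phenotype)` per pathway with
   broom-style `tidy()`/`glance()` and `autoplot()` methods.

A first-class synthetic-data module (`synth_config()`, `synth_all()`)
generates every input — paired negative-binomial counts with planted DE
miRNAs, a stochastic-block-model network, two overlapping target databases,
module-aligned pathways, and hallmark labels with a planted logistic law —
so the entire pipeline is exercisable and testable offline.

## Worked example

```r
library(evnetprop)

dat <- synth_all(synth_config(seed = 42))   # all inputs + ground truth
de  <- run_de(dat$counts)                   # filter -> TMM -> paired test
#> expression filter: retained 299 of 300 miRNAs (1 dropped)
sum(de$call != "not_de")
#> [1] 16

seeds <- build_seed_set(de, dat$targets)    # cross-database consistent targets
nrow(seeds)
#> [1] 38

runs  <- propagate_all(dat$network, seeds, r = 0.7, k = 20)
pcnt  <- perturbation_counts(runs, dat$gene_sets)
fit   <- hallmark_association(pcnt, dat$hallmarks)
tidy(fit)
#> # A tibble: 2 × 7
#>   term  estimate std_error statistic   p_value conf_low conf_high
#>   <chr>    <dbl>     <dbl>     <dbl>     <dbl>    <dbl>     <dbl>
#> 1 beta0  -1.31      0.314      -4.16 0.0000318  -1.92      -0.691
#> 2 beta1   0.0627    0.0211      2.97 0.00300     0.0213     0.104
```

16 miRNAs are called differentially expressed (the 16 planted ones), their
cross-database-validated targets give 38 seed genes, and pathways hit by
more propagation runs have significantly higher odds of carrying an
aging-hallmark label (β₁ > 0, p ≈ 0.003): the planted association is
recovered. `autoplot(de)`, `autoplot(runs[[1]]$profile)` and
`autoplot(fit)` draw the volcano, affinity-decay and logistic-curve
figures.

`run_pipeline(pipeline_config(...))` executes the same chain from files
(counts/metadata/target TSVs, edge-list TSV, GMT), writes every
intermediate table plus a JSON run manifest with per-stage counts, and a
thin CLI lives at `inst/cli/evnetprop.R`. For an archival reanalysis,
point the config at a GEO supplementary miRNA count export and a
tissue-network edge-list download; `?pipeline_config` documents the
stage parameters.

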