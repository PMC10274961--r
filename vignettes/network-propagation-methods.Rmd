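---
title: "From exercise-responsive EV miRNAs to cartilage-aging hallmarks: methods"
author: "evnetprop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From exercise-responsive EV miRNAs to cartilage-aging hallmarks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evnetprop)
```

# The inference chain

Circulating extracellular vesicles (EVs) carry miRNA cargo between tissues,
and an acute bout of exercise changes which miRNAs they carry. `evnetprop`
implements the computational chain that turns a paired small RNA-seq count
table of EV miRNAs into a statement about cartilage aging:

1. **Differential expression** — filter low-count miRNAs, normalize by TMM
   and counts-per-million, and test each miRNA's paired post-minus-pre
   contrast, calling miRNAs at |log2FC| > 1 and p < 0.05.
2. **Target seeding** — intersect per-miRNA target predictions across two
   databases (one prediction-style, one carrying experimental-evidence
   labels), keep strong-evidence interactions, and take the deduplicated
   union over the DE miRNAs as the seed gene set.
3. **Propagation** — run a random walk with restart (RWR) from each seed
   gene over a weighted tissue-specific functional gene network, yielding a
   per-seed affinity profile and its top-k vicinity.
4. **Enrichment** — score pathway over-representation of the propagated
   gene sets by the one-sided hypergeometric test with BH FDR, and count,
   for each pathway, how many seed runs perturb it.
5. **Hallmark association** — regress binary cartilage-aging hallmark
   labels on the per-pathway perturbation counts by logistic regression and
   report the fitted probability of the aged phenotype.

Each stage is an exported function working on plain data frames;
`run_pipeline()` chains them through files, so every stage can be rerun or
audited independently.

# The random walk with restart

Given a weighted undirected network with adjacency $A$, the walk uses the
column-stochastic operator $W_{ij} = A_{ij} / \sum_k A_{kj}$ and iterates

$$p^{(t+1)} = (1 - r)\,W p^{(t)} + r\,e,$$

where $e$ is uniform over the seed genes and $r \in (0,1)$ is the restart
probability. The fixed point $p = r\,(I - (1-r)W)^{-1} e$ exists and is
unique because $(1-r)W$ has spectral radius below 1; `rwr()` exposes both
the iteration (L1 tolerance $10^{-10}$, the default) and the direct solve
(`method = "exact"`), and the test suite holds them to within $10\times$ the
iteration tolerance of each other. A node's stationary probability — its
*affinity* — measures functional closeness to the seed.

Numerical and structural choices:

* **Restart probability** defaults to $r = 0.7$, the convention of widely
  used RWR implementations; it is a first-class parameter because it sets
  the locality of the diffusion. At $r \to 1$ all mass returns to the seed;
  at $r \to 0$ the walk forgets the seed and approaches the
  weighted-degree-proportional stationary law. A consequence worth knowing:
  on a path seeded at an endpoint, the seed's higher-degree neighbour
  overtakes the seed itself once $r$ is small (below roughly 0.25), while
  affinity still decays strictly with distance among non-seed nodes at any
  $r$.
* **Connectivity.** A degree-zero column breaks stochasticity, so the
  network constructor keeps only the largest connected component and
  reports what it dropped. (The only exception is a deliberately
  single-node network, where the walker simply stays put.) Duplicate edges
  collapse to their maximum weight; self-loops are removed.
* **"Affinity > 0" versus top-k.** On a connected component every non-seed
  node has strictly positive affinity, so a positivity threshold selects
  the whole network. Both readouts are implemented —
  `pseudo_activated()` with an explicit threshold, and `top_k_vicinity()`
  with $k = 20$ by default — and the pipeline feeds the vicinity to the
  enrichment stage, which is the well-defined choice. Vicinity ties break
  lexicographically by gene identifier so results are reproducible
  bit-for-bit.

# Differential expression details

The filter retains miRNAs whose CPM exceeds the CPM-equivalent of
`min_count = 10` (relative to the median library size) in at least the
smallest-group number of samples and whose total count is at least
`min_total = 15`; with more than ten samples per group the required number
grows with proportion 0.7. TMM factors are computed against the sample
whose upper-quartile CPM is closest to the mean, with two-sided trimming of
M-values (30%) and A-values (5%) and inverse-variance weighting, then
renormalized to geometric mean one. log-CPM uses a prior count of 0.5
scaled by effective library size.

The paired test works on per-subject post-minus-pre differences of log-CPM.
With shrinkage on (the default), per-miRNA variances are moderated toward a
pooled scaled-inverse-chi-squared prior whose parameters $(d_0, s_0^2)$ are
fitted by method of moments — matching the first two moments of the sample
variances under the implied F marginal — and the moderated t uses
$d + d_0$ degrees of freedom. This is a deliberate simplification of the
iterative profile fit used by the classic empirical-Bayes packages; on the
data sizes targeted here the two agree at the set level (the tests check
>95% call agreement against an independent reference), though borderline
p-values can differ. DE calls use the raw p-value with the |log2FC| > 1
threshold; BH q-values are always reported alongside. The fold-change rule
is applied to the absolute value, since a down-regulated miRNA is as
eligible as an up-regulated one.

Logistic hallmark association is fitted by Newton–Raphson on the Bernoulli
log-likelihood with step-halving (the log-likelihood never decreases),
Wald standard errors from the inverse observed information, and an explicit
error on complete separation — with as few as eight hallmark pathways a
separation is easy to produce, which is why the synthetic default uses 100
pathways and `hallmark_association()` warns below 30.

# What the synthetic generator emulates

The generator produces every pipeline input with planted ground truth, so
the whole chain has a parameter-recovery test surface:

* **Counts**: negative-binomial (variance $\mu + \mu^2\phi$, $\phi = 0.1$ by
  default — a typical small RNA-seq dispersion), ten subjects sampled at
  two timepoints (optionally three), library sizes uniform on
  $[8\times10^5, 1.2\times10^6]$, a subject-level random effect (SD 0.2 on
  log2 scale) that makes pairing informative, and 16 planted DE miRNAs
  shifted by $2^{2.0}$ post-exercise. Planted DE miRNAs are drawn from the
  upper half of the abundance distribution so the planted effect is
  identifiable above the count-noise floor.
* **Network**: a stochastic block model over 400 genes in 8 modules
  (within-module edge probability 0.15, between 0.005, weights uniform on
  (0.05, 1]). The SBM was chosen over scale-free alternatives because block
  membership doubles as a checkable functional ground truth: propagation
  from a module gene should concentrate affinity in that module.
* **Target maps**: two databases; true targets of DE miRNAs are drawn from
  one planted module and appear in both databases with probability 0.8
  (the cross-database agreement rate), decoys are unique to one database.
* **Pathways and hallmarks**: 100 module-aligned gene sets (sizes 10–30);
  each pathway's hallmark label is Bernoulli with
  $\mathrm{logit}\,p = \beta_0 + \beta_1 x$, $(\beta_0, \beta_1) =
  (-1, 0.15)$, where $x$ is the pathway's count of planted-module genes —
  the quantity the pipeline's perturbation count estimates.

Every generator stage derives its own RNG stream from the config seed, so
identical configs reproduce all artifacts bit-identically and stages can be
regenerated independently.

What the generator does **not** emulate: read-level sequencing artifacts
(no FASTQ, no mapping ambiguity), isomiR structure, correlated miRNA
families, hub-dominated degree distributions, annotation bias in real
pathway databases, and the version drift of live target databases. Passing
the planted-recovery tests therefore demonstrates that the chain's logic
and statistics are correct under its stated assumptions — not that any
particular biological dataset will behave as cleanly.

# Problem sizes and test design

The simulation studies in the test-suite and the acceptance script use the
default generator sizes above: 50 replicate datasets for DE sensitivity
(planted log2FC = 2 at n = 10 pairs; sensitivity well above 0.9), 100
replicate end-to-end runs for planted-pathway recovery (the module-aligned
pathway carries the top perturbation count and FDR < 0.05 in ≥95% of
replicates), and 100 replicates at 200 pathways for logistic parameter
recovery (estimates within 3 SE of the planted coefficients in ≥95%).
These sizes give binomial standard errors of a few percent on each rate
while keeping a full run in the low minutes on a laptop.

# Real-data runs

The pipeline reads plain formats throughout — a miRNA × sample count TSV
(such as a GEO supplementary export), a 3-column weighted edge list (the
format tissue-network servers provide for download), target maps as TSV and
pathways as GMT — so an archival reanalysis is a `pipeline_config()`
pointing at those files. Two analysis choices are surfaced because the
archival design leaves them open: which post-exercise timepoint defines the
paired contrast (`timepoints` argument; immediately-post by default), and
whether seeding uses all DE miRNAs or up-regulated ones only
(`direction_filter`; all DE by default — empirically equivalent when the
down-regulated miRNAs contribute no cross-database-consistent target).
Target-database contents are deliberately treated as input fixtures, never
fetched live: target counts are tied to database versions and would not be
reproducible otherwise.

# Known limitations

* The moderated test's method-of-moments prior fit can differ from the
  exact iterative empirical-Bayes fit near the calling thresholds;
  conclusions should be drawn at the set level.
* Perturbation counts in the default seed-run mode saturate at the number
  of seeds; with many seeds and small networks the predictor can lose
  resolution (the gene-overlap mode is available as an alternative).
* The logistic model is single-predictor by design; no penalized fallback
  is provided, so separated inputs are an error, not an estimate.
* RWR is single-network; multiplex or heterogeneous-network variants are
  out of scope.
```{r session}
sessionInfo()
```
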