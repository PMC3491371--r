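# stemsig

Anchor-specific gene-signature discovery and single-sample "stemness"
scoring for bulk and single-cell expression matrices.

## The problem

Given a heterogeneous compendium of expression profiles in which a minority
of samples carry a phenotype of interest (the *anchor* class — pluripotent
stem cells in the motivating application), find the genes whose expression
is most *specific* to that class, and turn their joint activity into a
per-sample score that orders all samples along the anchor–non-anchor axis.

A mean-shift contrast (t-test) is the wrong tool for this: in a diverse
compendium, the non-anchor samples may express a gene at simultaneously
*higher and lower* levels than the anchors, so group means coincide even
when the anchor class occupies a distinctively narrow expression band.

## The statistic

For one gene with values $x_1,\dots,x_S$ and anchor indicators
$a_1,\dots,a_S$ ($\sum a_i = A$), sort the samples by value and slide a
window of fixed width $W$ (by default $W = A$) over the sorted list. The
gene's score is

$$\mathrm{score} = \max_{w} \frac{1}{W} \sum_{i \in w} a_i ,$$

the greatest fraction of anchor samples that any one window can localize.
A score of 1 means every anchor fits in a single band of $W$ consecutive
expression values. Each score is accompanied by the binomial tail
$P(X \ge k)$, $X \sim \mathrm{Bin}(n{=}W,\ p{=}A/S)$, where $k$ is the
anchor count in the best window. Scoring operates on per-sample fractional
ranks ($r/G$ for $G$ genes), which makes it invariant to any monotone
transform of the intensities and comparable across data series.

The top-ranked genes form a signature; its coordinated activity is
summarized per sample by projection onto the leading eigenvector of the
signature's gene–gene covariance matrix (mean-centered genes, no variance
scaling). That PC1 coordinate is the **stemness index**, sign-oriented so a
chosen group (e.g. pluripotent) scores high. The index is refit
independently within each external series, and evaluated against ordered
phenotypes (differentiation stage, tumor grade) by Spearman correlation
and pairwise rank-sum AUC.

## Worked example

Discover a signature on a synthetic landscape with planted structure and
score every sample:

```r
library(stemsig)

sim    <- simulate_landscape(landscape_config(seed = 7))
x      <- rank_normalize(sim$matrix)
scores <- rank_genes(x, sim$pheno)
print(scores, n = 5)
#> Anchor-specificity gene ranking: 2000 genes, window W = 40, anchor fraction = 0.1
#>   gene_id score k_best window_start  p_value rank
#> 1   g1645 1.000     40          187 1.00e-40    1
#> 2   g0217 0.975     39          173 3.61e-38    2
#> 3   g0378 0.975     39          186 3.61e-38    2
#> 4   g0397 0.975     39          193 3.61e-38    2
#> 5   g0646 0.975     39          179 3.61e-38    2
#> ... 1995 more genes

sig <- select_signature(scores, top_n = 60)
fit <- compute_stemness(x, sig, orientation_group = "pluripotent",
                        pheno = sim$pheno)
print(fit)
#> Stemness index over 60 signature genes, 400 samples
#> PC1 variance explained: 60.5%
#> Oriented so group 'pluripotent' has mean index >= 0
#> Index range: [-1.151, 1.278]

round(tapply(fit$index[sim$pheno$sample_id], sim$pheno$group, mean)[
  c("pluripotent", "multipotent", "progenitor", "cancer", "normal")], 3)
#> pluripotent multipotent  progenitor      cancer      normal
#>       1.137       0.743       0.367      -0.122      -0.812
```

The score table reads: gene `g1645` places all 40 anchor samples inside one
window of 40 consecutive expression ranks (score 1.0, binomial tail
1e-40), so its expression is maximally specific to the anchor class. The
fitted index captures 60.5% of the signature's covariance and its group
means descend along the planted differentiation gradient — pluripotent
highest, normal tissue lowest.

An end-to-end run (simulate → normalize → score → sweep → select → index →
characterize) is one call: `run_pipeline(config)` with a YAML or list
configuration; see `?run_pipeline`. A thin command-line wrapper is
installed at `inst/scripts/stemsig.R`.

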