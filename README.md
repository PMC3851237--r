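# circnet

Circadian transcriptome network analysis in R: cosinor rhythmometry,
multi-evidence interaction networks, consensus centrality and
closeness-scaled clustering of expression contrasts.

## The problem

Fibroblast cultures carry a cell-autonomous circadian clock. In a lysosomal
storage disease such as Hunter syndrome (iduronate-2-sulfatase deficiency),
the expression of core clock genes and their downstream clock-controlled
genes is perturbed, and enzyme replacement modifies it over time. An
analysis of such an experiment has three layers, all implemented here:

1. **Differential expression across five contrasts** — disease vs control
   (H/C), treated cells at 24 h and 144 h vs control (T1/C, T2/C) and vs
   untreated disease cells (T1/H, T2/H). Ratios r are reported as signed
   fold changes (r if r ≥ 1, else −1/r), qRT-PCR assays as 2^−ΔΔCt, with
   p < 0.001 (sequencing) / p < 0.05 (qRT-PCR) significance filters and a
   PCA-based screen that keeps the genes varying most along the first three
   principal axes.

2. **Rhythmometry** — each serum-shock time course y(t) is fitted by the
   single cosinor, y = M + β·cos(ωt) + γ·sin(ωt) with ω = 2π/24 h, giving
   the MESOR M, amplitude A = √(β² + γ²), acrophase φ = atan2(γ, β) in
   positive degrees (15°/h of peak time), R² and the zero-amplitude F-test
   F = (MSS/2)/(RSS/(n−3)) on (2, n−3) df, plus polarogram export.

3. **Network centrality and clustering** — heterogeneous interaction
   evidence (protein domains, co-expression, genetic, pathways, physical,
   predicted) forms a signed, weighted hypergraph; parallel evidences of a
   pair agglomerate into one edge with weight **W_AB = eⁿ · mean(W_i)** over
   the n evidences, so multiply-evidenced pairs dominate. Five topology
   indices (weighted closeness and betweenness over 1/W path lengths,
   normalized strength, local clustering, a bounded-walk topological
   importance index) feed a consensus rule: a gene is central when ≥ 4 of
   the 5 indices rank it in their top 26. Fold-change profiles scaled by
   closeness are clustered (squared Euclidean, Ward) and tested for gene-set
   over-representation (hypergeometric upper tail, Benjamini–Hochberg).

The study data behind this design are not publicly deposited, so the package
includes a synthetic-data generator (`gen_contrast_profiles()`,
`gen_timeseries()`, `gen_evidence_hypergraph()`, `gen_annotation_sets()`)
that emulates the design with planted ground truth — clusters, rhythm
parameters, hub genes — against which every stage is recovery-tested.

## Worked example

```r
library(circnet)

# Cosinor fit: 6 sampling times x 3 replicates, planted peak at 4 h
t <- rep(c(1, 4, 10, 16, 22, 28), each = 3)
set.seed(42)
y <- 0.6 + 0.4 * cos(2 * pi * (t - 4) / 24) + rnorm(length(t), 0, 0.05)
fit_cosinor(t, y)
#> cosinor fit (period 24 h, n = 18): MESOR 0.6252, amplitude 0.374,
#>   acrophase 64° 46′, R2 0.964, p = 1.349e-11 (significant)
```

The fitted MESOR (rhythm-adjusted mean), amplitude and acrophase recover the
planted 0.6 / 0.4 / 60° within the noise; the tiny zero-amplitude p-value
says a 24-h rhythm is clearly present.

```r
# Evidence agglomeration: AHR-HIF1A is supported by two evidences
ev <- data.frame(gene_a = c("AHR", "AHR", "AHR", "CRY1"),
                 gene_b = c("HIF1A", "HIF1A", "CRY1", "HIF1A"),
                 category = c("physical", "pathways", "coexpression", "pathways"),
                 weight = c(0.9, 0.7, 0.8, 0.6), sign = c(1L, 1L, 1L, -1L))
g <- agglomerate(build_hypergraph(ev))
g$edges
#>   from    to   weight n_evidence sign
#> 1  AHR  CRY1 2.174625          1    1
#> 2  AHR HIF1A 5.911245          2    1
#> 3 CRY1 HIF1A 1.630969          1   -1
weighted_closeness(g)
#>      AHR     CRY1    HIF1A
#> 8.085870 3.805595 7.542214
```

The doubly evidenced pair gets weight e²·mean(0.9, 0.7) ≈ 5.91 versus
e·0.8 ≈ 2.17 for a single evidence; AHR, sitting on both reliable edges, is
the most central node.

## The analysis workflow

The numbered drivers under `analysis/` run the full study-shaped analysis on
synthetic data (190 genes, 5 planted clusters, 6 evidence categories, one
planted hub; fixed seed), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # inputs + ground truth
Rscript analysis/02_expression_screen.R # significance filter + PCA screen
Rscript analysis/03_rhythms.R           # cosinor table + polarogram
Rscript analysis/04_network.R           # hypergraph -> weighted graph
Rscript analysis/05_topology.R          # 5 indices + consensus centrals
Rscript analysis/06_clusters.R          # scaled clustering + enrichment
```

A run prints, e.g., `network: clustering coefficient = 0.133, connected
components = 1, diameter = 4, characteristic path length = 2.014, density =
0.137 ...` for the agglomerated network and `adjusted Rand index against the
planted clusters: 1.000` for cluster recovery. The same stages are callable
in one step via `run_all(pipeline_config(...))`, which writes every artifact
plus a hash-stable `manifest.json`.

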