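# rccprofiler

Comparative expression profiling of renal tumor subtypes against matched
normal tissue, built for the question: *is a rare tumor subtype (such as
the FLCN-mutant kidney tumors of Birt–Hogg–Dubé syndrome) molecularly
distinct from the sporadic subtypes it histologically resembles, and
what transcriptional program sets it apart?*

The package implements the complete analysis stack as composable, seeded
stages over plain-text formats (TSV, GMT, UCSC cytoBand, Newick):

* **Normalization** — technical-replicate averaging and matched-normal
  log-ratios: `z_gj = y_gj − mean(y_g, normals of the sample's tissue)`.
* **Variance filtering & clustering** — IQR gene filtering (type-7
  quantiles), Euclidean complete/average-linkage clustering, and
  gene-resampling **bootstrap probabilities** for node support
  (`BP = 100 · #{replicate trees containing the node} / B`).
* **Moderated-t differential expression** — per-gene pooled variances
  shrunk toward an empirical-Bayes prior
  `s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g)`, with
  `t̃ = Δz̄ / (s̃_g √(1/n_A + 1/n_B))` on `d₀ + d_g` df, the prior
  `(d₀, s₀²)` fitted by moments on log variances via trigamma inversion;
  Benjamini–Hochberg FDR.
* **Distinctness permutation test** — for unbalanced designs: repeatedly
  draw `k` of the pool and compare DE counts between focal-vs-draw and
  draw-vs-rest, reporting the exceed fraction (ties count ½) and the
  add-one bound `p ≤ (#{within ≥ between} + 1)/(B + 1)`.
* **Per-sample parametric gene set enrichment** — the one-sample t of a
  set's member ratios within each sample: `mean(z)/ (sd(z)/√|S|)`.
* **Expression-inferred cytogenetics** — chromosome arms as gene sets;
  a per-sample arm with enrichment `p < 0.001` is called a gain or loss
  by the sign of its mean shift.
* **Gene-set dissimilarity** — `D(A,B) = 1 − (N_A∩B/2)(1/N_A + 1/N_B)`
  with average-linkage set clustering, and dual-definition percent
  similarity (Jaccard and `100·(1−D)`).
* **Signatures & correlation screens** — FDR + fold-change thresholded
  up/down signatures; Spearman screens of a driver gene against all
  per-sample enrichment scores; Pearson comparison of signature score
  vectors.
* **Synthetic cohorts** — `simulate_cohort()` plants subtype marker
  programs, arm-level dosage shifts, gene-set activations and a
  driver–pathway coupling with known ground truth, reproducibly from one
  seed.

## Worked example

Simulate a study-shaped cohort — subtypes of 6 ("BHD"), 11 ("ON") and
12 ("CH") tumors plus 12 matched normals, the 6-sample subtype carrying
an OXPHOS-like gene-set activation and a driver gene negatively coupled
to it, the others carrying arm losses — and run every stage:

```r
library(rccprofiler)
cohort <- simulate_cohort(cohort_design(n_genes = 4000, seed = 9900))
res <- run_pipeline(cohort, params = list(boot_B = 200, perm_B = 100), seed = 13)
print(res)
#> PipelineResult
#>   focal subtype: BHD (6 samples)
#>   DE genes vs others (FDR < 0.01): ON = 512, CH = 1089
#>   focal clade BP: 100 (B = 200)
#>   distinctness: exceed_fraction = 1.000, p_bound = 0.009901
#>   planted set rank(s): OXPHOS_LIKE = 1
#>   arm-call sensitivity: 1.000, null call rate: 0.0000
#>   coupling: target OXPHOS_LIKE, rho -0.583 (planted -0.60), rank 1
```

Reading the report: the focal subtype is separated from the sporadic
subtypes by hundreds of DE genes at FDR < 0.01; its six samples form a
dendrogram clade supported in 100% of gene-resampled bootstrap trees;
the between-subtype DE count beat the within-pool count in every
permutation iteration, so the distinctness is not a sample-size
artifact (p ≤ 1/(B+1)); the planted mitochondrial-like set tops the
discriminant-set ranking; every planted arm loss is called with no
false calls on unaffected arms; and the driver-versus-enrichment screen
ranks the coupled set most negative:

```r
head(as.data.frame(res$screen), 3)
#>              set        rho            p rank
#> 1    OXPHOS_LIKE -0.5834495 6.234638e-05    1
#> 2       PGC_LIKE -0.5313589 3.506238e-04    2
#> 3 RANDOM_SET_002 -0.3742160 1.593708e-02    3
```

With `out_dir =` set, every stage writes its table (normalized ratios,
Newick dendrogram with BP labels, DE tables, permutation trace,
enrichment matrix, arm calls, dissimilarity matrix, signature GMT,
correlation screen) plus a `config.yaml` recording all parameters.

A thin command-line wrapper with per-stage subcommands
(`simulate | normalize | cluster | diffexp | permtest | enrich |
armcalls | setdissim | signature | correlate | run-all`) is installed at
`inst/cli/rccprofiler.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/rccprofiler.R", package = "rccprofiler"))')" \
  run-all --n-genes 4000 --seed 9900 --out out/
```

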