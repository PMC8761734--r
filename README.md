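# tfnominate

Nominating a direct upstream transcription factor (TF) of a target gene
from paired ATAC-seq chromatin accessibility and RNA-seq expression
profiles of the same samples.

## The problem

Correlation screens on expression data alone can say that a gene tracks a
pathway, but not *who regulates it*. When matched accessibility data are
available, the regulatory question becomes concrete: if a TF drives a
gene, the TF's expression should co-vary with the openness of the
chromatin it binds, at the gene's promoter, across patients — and the
binding itself should be visible in ChIP-seq. `tfnominate` implements
that multi-omics screen end to end:

1. **Peak annotation** — every accessibility peak is assigned its
   nearest-TSS gene and a promoter category, `Promoter (<=1kb)` or
   `Promoter (1-2kb)` within a TSS window of (−2000, +2000) bp,
   `Other` beyond it.
2. **Promoter filter** — only promoter-category peaks are kept.
3. **Target-peak selection** — promoter peaks whose interval overlaps the
   target gene's locus are the candidate regulatory regions.
4. **TF screen** — each TF's expression is correlated (Pearson) with the
   target peak's accessibility over the matched samples; candidates must
   pass |r| > 0.2 and p < 0.01 and are ranked by |r|. For a TF expression
   vector x and peak accessibility a over n samples,
   r = Σ(xᵢ−x̄)(aᵢ−ā) / √(Σ(xᵢ−x̄)² Σ(aᵢ−ā)²), with the two-sided p-value
   from t = r√((n−2)/(1−r²)) on n−2 df.
5. **ChIP support** — a candidate is supported when its ChIP-seq peaks
   (merged) overlap the target peak by at least 1 bp; an optional
   overexpression direction check closes the loop.

The package also ships the supporting computations such a study needs:
single-sample gene-set enrichment (ssGSEA) scoring of immune-cell
signatures with a Wilcoxon tumor-vs-normal comparison, a Spearman screen
of a receptor family (e.g. GPCRs) against an infiltration score,
Kaplan–Meier/log-rank survival analysis with the maximally selected
optimal cutpoint (the split maximizing the standardized log-rank
statistic |O−E|/√V), a follow-up filter (> 90 days), and Cox
proportional-hazards fitting with Harrell's C — plus a synthetic-data
generator that plants a TF → promoter-peak → target-gene chain, immune
marker structure and survival effects so the whole analysis can be
validated against known ground truth without any external data.

## Worked example

Simulate a study (41 tumor samples with paired accessibility/expression,
50 TFs, a planted driver at true r = 0.6) and run the pipeline:

```r
library(tfnominate)
dir <- file.path(tempdir(), "demo")
sim <- simulate_study(sim_config(seed = 1), dir)
report <- run_tf_pipeline(file.path(dir, "config.yaml"))
print(report)
#> TF nomination report for TARGET1 (candidates nominated)
#>   peaks: 200 total, 129 promoter, 1 on the target locus
#>   top candidates:
#>     peak_id tf_id        r            p  n chip_overlap_bp chip_supported
#> 1 peak_0136 TF001 0.628775 1.069987e-05 41             501           TRUE
```

Reading the output: of 200 accessibility peaks, 129 fall in a promoter
category and exactly one of those overlaps the target gene's locus — the
planted promoter peak. Screening all 50 TFs against that peak's
accessibility ranks the planted driver `TF001` first (sample r = 0.63,
p = 1.1e-05 at n = 41, comfortably past the |r| > 0.2, p < 0.01
thresholds), and its ChIP-seq peaks overlap the candidate peak by 501 bp,
so the nomination is binding-supported — the generator's ground truth
(`truth.json`) confirms it.

The same stages are available as a command line
(`inst/scripts/tfnominate`): `simulate`, `annotate`, `ssgsea`,
`screen-gpcr`, `tf-screen`, `chip-support`, `survival`, `run-all`.

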