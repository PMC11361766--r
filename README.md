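# m6adecay

Count-level analysis of how N6-methyladenosine (m6A) loss stabilizes
transcripts. The package implements, as tested and reusable R functions,
the full quantitative chain used to connect MeRIP-seq methylation calls to
RNA decay kinetics in disease-versus-control neuronal transcriptomes:

1. **MeRIP-seq differential methylation** — IP-vs-input enrichment per
   feature, a two-proportion z-test on pooled depth-normalized counts for
   the condition contrast (with a composition correction), BH adjustment,
   and hypo/hyper classification at FDR < 0.01.
2. **Spike-in calibrated RNA half-life estimation** — under
   transcription shutoff, dC/dt = −K·C, so ln(C/C0) = −K·t and
   t½ = ln2/K. Because total RNA mass falls during the time course,
   within-library CPM is converted to absolute attomole amounts by
   per-sample log–log regression on ERCC-style spike-ins; K is the mean of
   the per-timepoint estimates over the 0/3/6 h design.
3. **Expression and group-shift statistics** — median-of-ratios
   normalization, Welch tests per gene, and two-sided Wilcoxon rank-sum
   comparisons of log2 fold-change or half-life distributions between
   hypomethylated and non-hypomethylated gene groups (exact enumeration at
   small n, tie/continuity-corrected normal approximation at scale).
4. **Reader-target integration** — RIP-seq target calling (significantly
   RIP-enriched, upregulated-only), and two-tailed Fisher's exact tests of
   set overlaps (e.g. hypomethylated genes × reader targets) over a stated
   gene universe.
5. **Bench-assay quantifications** — spike-normalized MeRIP-RT-qPCR fold
   enrichment, 2^−ΔΔCt relative expression, LC-MS/MS m6A/A ratios via
   standard-curve calibration, and a proteomic z-score screen with
   missingness filtering and batch-control normalization.

A synthetic-data generator (`simulate_*`) produces all of these assays
from a known ground truth — per-gene methylation levels, a hypomethylated
gene set, reader-binding labels, and condition-wise first-order decay
rates coupled to methylation — so every stage of the pipeline can be
validated closed-loop. See the methods vignette
(`vignettes/m6adecay-methods.Rmd`) for the model and all design choices.

## Worked example

```r
library(m6adecay)

res <- run_simulation_study(simulation_params(seed = 1))
res$report
#> integration_report: 2000 genes
#> expression shift (hypo vs non-hypo): delta median log2fc = 0.302, p = 3.42e-45
#> half-life shift (hypo genes, patient vs control): median ratio = 1.21, p = 7.46e-20
#> hypo x target overlap: 266 shared, OR = 5.31, Fisher p = 2.27e-39

table(res$calls$class)
#>     hyper      hypo unchanged
#>         4       345      1651

head(subset(res$halflife, condition == "patient"), 3)[,
     c("gene_id", "c0_attomole", "k_per_h", "halflife_h")]
#>        gene_id c0_attomole k_per_h halflife_h
#> 2001 gene_0001        1.69   0.112       6.19
#> 2002 gene_0002        4.30   0.112       6.20
#> 2003 gene_0003        5.79   0.198       3.50
```

Reading the report: hypomethylated genes are up-shifted in expression
relative to everything else (positive median log2 fold change, Wilcoxon
p ≪ 0.01), their half-lives are ~20% longer in the patient condition
(rank-sum p ≪ 0.01), and they overlap the called reader targets far more
than chance (Fisher p ≪ 0.01) — the three qualitative findings the
analysis chain is built to detect, here recovered from data simulated with
exactly those properties.

Individual stages are plain functions over a `count_matrix` (counts plus
sample metadata): `differential_methylation()`, `estimate_decay()`,
`differential_expression()`, `call_rip_targets()`, `integrate_report()`,
and the I/O helpers `read_count_matrix()` / `write_count_matrix()` for
TSV round trips.

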