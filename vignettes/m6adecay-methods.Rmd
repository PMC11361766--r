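---
title: "Models and methods behind m6adecay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind m6adecay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6adecay)
```

# The scientific problem

N6-methyladenosine (m6A) marks transcripts for accelerated turnover:
reader proteins such as YTHDF2 bind methylated mRNAs and route them to
decay. When methylation is lost — as reported in C9ORF72-ALS/FTD neurons —
bound transcripts escape this route, their half-lives lengthen, and their
steady-state abundance rises. Establishing that chain from sequencing data
requires four quantitative steps that this package implements end to end:
calling differential methylation from MeRIP-seq counts, measuring decay
kinetics absolutely (spike-in calibrated) under transcription shutoff,
comparing expression and half-life distributions between gene groups, and
testing the overlap of hypomethylated genes with reader targets.

Real patient datasets cannot be regenerated at desk scale, so the package
ships a generative model with known ground truth. All statistical claims
made by the test suite are claims about that model; the section on the
simulator's scope below says what that does and does not establish.

# The generative model

Each gene $g$ carries a methylation level $m_g \in [0,1]$: a point mass at
0 (fraction `unmethylated_fraction`, default 0.4) and a Beta(2, 2) draw
otherwise, giving a broad mid-range of methylation with few extreme
values. Methylated genes are bound by the reader with probability
`target_fraction` (default 0.8 — readers bind the large majority of
methylated transcripts; the remainder models methylated sites outside the
reader's preference). A fraction `hypo_fraction` (default 0.3) of
methylated genes is hypomethylated in the patient condition: their $m$ is
multiplied by `hypo_effect` (default 0.4).

Decay is first order. For reader-bound genes the rate couples to
methylation,

$$K = K_0 + \beta m, \qquad K_0 = 0.12\ \mathrm{h^{-1}},\ \beta = 0.15\ \mathrm{h^{-1}},$$

so control half-lives span roughly 2.6–5.8 h, in the range typical of
neuronal mRNA. Unbound genes decay at $K_0$ regardless of $m$: methylation
only matters through the reader. Hypomethylation therefore lowers $K$
exactly for hypomethylated reader targets and nothing else.

Under constant synthesis $s_g$ and first-order decay, steady state is
$C = s_g / K$. The simulator anchors the control steady state at
$C_{0,g}$ (log-normal, median 5 attomole) and sets the patient steady
state to $C_{0,g} \cdot K_{\mathrm{control}} / K_{\mathrm{patient}}$. This
is the mechanism by which stabilization *is* upregulation in the model —
the decay time course starts at each condition's steady state, and the
t = 0 libraries double as the expression (RNA-seq) data for the
group-shift analysis.

## Count noise and its dependence structure

Counts are negative binomial with one shared dispersion
$\phi$ (default 0.05, i.e. a biological CV of ~22%), generated as a
gamma latent $A_{g,r} \sim \Gamma(1/\phi, 1/\phi)$ (mean 1) times a
Poisson draw around the depth-scaled expected proportion. Marginally every
count is exactly NB$(\mu, \phi)$.

The latent is *shared* where the experiment shares material:

* between the IP (or RIP) and input library of one replicate — both are
  fractions of the same RNA sample, so a gene's biological fluctuation
  appears in both and cancels in the enrichment ratio;
* across the timepoints of one decay replicate — one cell line followed
  through the time course, so the trajectory of a replicate is a clean
  exponential from its own starting point while replicates differ.

This matched structure is what makes ratio-based inference (two-proportion
tests on pooled counts, per-replicate log-ratios, within-replicate decay
slopes) behave the way the corresponding real designs do. Spike-in counts
get independent latents per sample (pipetting noise).

Library depth is drawn per library (log-normal, CV 0.1 around
2 × 10⁶ reads), and IP/RIP libraries are renormalized to their own depth —
enrichment is only recoverable relative to input after depth
normalization, as in real data.

## Spike-ins and absolute scale

Decay samples contain 92 spike-in species log-spaced over 0.05–50
attomole (about 4% of the library at t = 0, spanning three decades like a
commercial mix). Their amounts are constant across samples while the gene
mass decays, so within-library CPM is a moving target: a gene with
constant true abundance *gains* CPM as the library shrinks. Per-sample
calibration against the spike-ins is therefore not optional; the pipeline
exercises exactly the normalization problem that motivates spike-ins in
shutoff experiments.

# The analysis chain

## Differential methylation

For each condition, replicate-mean CPM per assay is rescaled to the pooled
class library size ("effective pooled counts"), and each feature's
IP-vs-input log-odds difference between conditions is tested with a
two-proportion z-test; a pseudocount of 0.5 keeps all log-ratios finite
(Haldane–Anscombe). p-values are BH adjusted; features are classified
`hypo`/`hyper` at FDR < 0.01 (strict inequality) by the sign of the delta.

One correction is essential: when a large cohort of genes loses
methylation, every other gene's *share* of the patient IP library rises,
so an uncorrected test calls spurious hypermethylation across the board.
The per-feature delta log-odds is therefore median-centered before testing
(implemented as a rescaling of one condition's IP library), under the
standard majority-unchanged assumption of median-of-ratios/TMM
normalization. Under the no-effect null the centering is a no-op up to
noise; the test suite checks both the null calibration (type-I fraction
inside the binomial 99% band) and, under the default effect sizes,
sensitivity and empirical FDR against ground truth.

Gene-level classes use the any-hypo-peak rule: a gene with at least one
hypomethylated peak is hypomethylated. Whether the "non-hypo" comparison
group should also exclude hyper-only genes is not obvious; the default
keeps them (`nonhypo_includes_hyper = TRUE`), and the switch exists
because the choice is a judgment call, not a derivable fact.

## Half-life estimation

Per sample: CPM, then ordinary least squares of log10(amount) on
log10(CPM) over detected spike-ins (at least 3 required), then conversion
of gene CPM to attomole. The log–log scale is chosen because the spike mix
spans decades — a linear-scale fit would be dominated by the largest
spikes; `calibration_scale = "linear"` is available.

Per gene and condition, attomole values are averaged over replicates at
each timepoint, and each later timepoint gives
$K_t = -\ln(C_t/C_0)/t$. The reported rate is the arithmetic mean of the
$K_t$ — the reading of "average over 0/3/6 h" that uses all three
timepoints and is exact for a true exponential (t = 0 defines $C_0$, so
two $K_t$ values are averaged). The alternative reading, averaging
per-timepoint half-lives, is available via
`halflife_average = "halflife"`; both coincide on noiseless data.

Genes with $K \le 0$ (apparent accumulation) are *censored*: reported with
a flag and excluded from rank tests, rather than clipped to an arbitrary
large half-life that would distort rank statistics. Undetected
(zero-count) gene–timepoint combinations are treated the same way at the
conversion step.

## Expression, shifts, overlaps

Differential expression is deliberately plain: the filter (≥ 10 reads in
≥ 3 samples), median-of-ratios size factors, Welch t on
log2(normalized + 0.5) across replicates, BH adjustment. The downstream
group-shift analysis needs only unbiased normalized log2 fold changes; no
dispersion shrinkage is attempted, and the test suite checks that the
Welch route is valid (not anticonservative) on a null simulation — it runs
mildly conservative at n = 3 + 3, which is the accepted cost of
simplicity here.

Group shifts use a two-sided Wilcoxon rank-sum test implemented in the
package: full enumeration of all group assignments for combined n ≤ 20
(valid under ties, where the classical exact distribution is not), and the
tie-corrected, continuity-corrected normal approximation beyond. Overlap
tests use the two-tailed Fisher's exact convention that sums the
probabilities of all tables no more probable than the observed one; the
reported odds ratio is the sample odds ratio ad/bc (with an infinity flag
at bc = 0), not the conditional MLE. The gene universe for overlap tests
is the set of genes passing the expression filter in the relevant
dataset — a choice that must be stated because odds ratios depend on it;
any other universe can be passed explicitly.

## Reader targets

RIP targets are the significantly RIP-*enriched* genes (adjusted
p < 0.05 and positive fold change — depleted genes are never targets).
Because each RIP library is immunoprecipitated from the same lysate as its
matched input, the default test is paired: the per-replicate log2
RIP/input CPM ratio, median-centered per replicate (the global enrichment
of the bound fraction is absorbed there), tested against zero across
replicates. The unpaired Welch route (`method = "unpaired"`) treats the
libraries as independent groups and is noticeably less sensitive at three
replicates; it is kept for designs without matched pairs.

## Bench assays

The qPCR helpers are pure arithmetic on cycle thresholds
(spike-normalized MeRIP fold enrichment; 2^−ΔΔCt). The MS m6A/A ratio
inverts two per-channel standard curves (signal regressed on
concentration) and refuses signals whose calibrated concentration is
non-positive. The proteomic screen removes proteins missing in more than
`max_missing` samples (default 4), optionally divides each protein by its
value in the designated batch-control sample, z-scores each protein across
*all* retained samples (sample sd; computing z within groups before
comparing them would build the group difference into the scaling), and
compares groups per protein by Wilcoxon. Missing values are never imputed;
zero-variance proteins are flagged and excluded from testing.

# Numerical and degenerate-input conventions

* Pseudocount 0.5 wherever a log-ratio is formed; configurable.
* All significance thresholds compare with strict `<`.
* Counts are stored as integers; normalized/calibrated values live in
  separate real matrices. The only exception is the simulator's noiseless
  mode, which emits continuous expected counts (exact proportionality to
  C(t) is impossible in integers) and marks the object accordingly.
* Welch tests on rows with zero variance in both groups return p = 1 when
  the means agree and p = 0 otherwise.
* A flat standard curve fits slope 0 with r² = 0 (defined, but unusable
  for inversion, which then errors).
* All generators are deterministic given (parameters, seed); derived
  seeds stay below 2³¹.

# What the simulator does and does not establish

The generator reproduces the *statistical structure* the analysis
assumes: NB counts with realistic dispersion, depth variation, matched
IP/input sampling, constant spike-ins against a decaying library,
methylation-coupled decay, and steady-state coupling of stabilization to
expression. Passing the closed-loop and operating-characteristic tests
shows the pipeline is correct and well calibrated *under that model*.

It does not emulate: peak-level coverage structure (features are whole
genes; coordinate-level peak calling is upstream and out of scope),
isoforms and 3'UTR switching, gene-specific dispersions, batch effects in
sequencing data, feedback of the disease process on the writer complex, or
partial/leaky transcription shutoff. Results on real data additionally
depend on alignment and counting choices that sit upstream of this
package.

# Problem sizes used by the shipped tests

The default simulation — 2000 genes, 92 spike-ins, 3 replicates per
condition, 2 × 10⁶ reads per library, 0/3/6 h — runs the full pipeline in
well under a second, so the regression suite can afford closed-loop
checks at full size, a 100-seed direction-reproduction study, exhaustive
Fisher enumeration over all 2 × 2 tables with margins ≤ 12, and a
1000-vector BH oracle comparison while staying within a few minutes end
to end. Monte-Carlo mean checks use a reduced 20-gene configuration at
400 replicate draws, sized so that three-standard-error bands are tight
relative to the means being verified.
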