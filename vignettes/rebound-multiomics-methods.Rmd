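---
title: "Methods: rebound multi-omics analysis of pregnancy-induced T-cell regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rebound multi-omics analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reboundomics)
```

## The problem

Pregnancy transiently dampens the activity of multiple sclerosis (MS),
with a characteristic worsening after delivery. At the molecular level
this shows up in circulating CD4+ and CD8+ T cells as a *rebound*: DNA
methylation and gene expression shift through pregnancy, peak around the
3rd trimester, and reverse post-partum. `reboundomics` implements the full
inference chain for detecting such rebound features in paired longitudinal
methylation/expression cohorts, expanding the genes they implicate into
protein–protein interaction (PPI) network modules, and quantifying
enrichment for disease-associated gene sets — together with a
synthetic-cohort generator with planted ground truth, so that every stage
can be validated by parameter recovery rather than by eyeballing.

## The statistical model

Each feature (CpG M-value or gene log-CPM) is modeled as

$$ y = \beta_0 + \beta_{d,t}\, s + \beta_a\, a + \beta_m\, m + \beta_c\, c + \varepsilon, $$

where $s$ indexes the combined (disease group, timepoint) cell, and $a$,
$m$, $c$ are age, memory-cell fraction and viability. Grouping disease and
time under one term gives each group its own time trajectory; contrasts of
the $\beta_{d,t}$ (3rd−1st trimester, post-partum−3rd, and optional
pre-pregnancy baselines) measure the effect of time within each group. A
group with no samples at some timepoint (the control group typically lacks
pre-pregnancy samples) simply contributes no column for that cell;
`build_design()` verifies full column rank and names any collinear column.

**Scales.** Methylation is tested on M-values, $M = \log_2 \beta/(1-\beta)$,
with $\beta$ clipped to $[10^{-6}, 1-10^{-6}]$; effect directions are
reported on the beta scale (positive mean beta difference =
hypermethylated). Expression is tested on log2 counts-per-million after a
CPM ≥ 10 in more than 30% of samples filter and trimmed-mean-of-M-values
(TMM) scaling-factor normalization (trim fractions 0.3 on log-ratios and
0.05 on average intensity, the estimator's published defaults, since no
others are stated for this workflow).

**Repeated measures.** Samples from one donor are correlated. Instead of a
per-feature random-effects fit, a single consensus intra-donor correlation
$\rho$ is estimated and absorbed by generalized least squares with a
block-equicorrelation covariance. The estimator works per feature from OLS
residuals $r = (I-H)y$: the within-donor off-diagonal sum
$S_1 = \sum_b \sum_{i \ne j \in b} r_i r_j$ and the residual sum of squares
$S_2$ have expectations linear in $\rho$ with coefficients that are traces
of known projection products ($\mathrm{tr}(P(I-H))$,
$\mathrm{tr}(P(I-H)B(I-H))$, …, with $B$ the donor-block indicator), so the
ratio $S_1/S_2$ inverts to a per-feature moment estimate that is corrected
for the hat-matrix projection. Without this correction the naive
"average pairwise residual correlation" is biased towards zero by roughly
$p/n$, which matters at the cohort sizes used here (~10 coefficients, ~80
samples). Per-feature estimates are Fisher-z transformed, averaged with 5%
tail trimming, and transformed back. Parameter-recovery tests confirm
$\hat\rho$ within ±0.1 of the generating value across
$\rho \in \{0, 0.3, 0.5, 0.7\}$ at 5,000 features.

**Precision weights.** Count heteroscedasticity is handled with
mean–variance precision weights: per-gene OLS on log-CPM, a `lowess`
smooth (span 0.5) of $\sqrt{\mathrm{sd}(\mathrm{residual})}$ against
average log2 count, and per-observation weights
$\widehat{\text{trend}}^{-4}$ evaluated at each observation's fitted log2
count. With fewer than 50 genes the trend is not estimable and uniform
weights are used (with a warning).

**Moderated statistics.** Residual variances are shrunk towards a common
prior by empirical Bayes: the first two moments of $\log s_g^2$ are
matched to a scaled F distribution via Newton inversion of the trigamma
function, yielding a prior df $d_0$ (possibly $+\infty$ when the observed
spread does not exceed chi-square sampling noise) and prior variance
$s_0^2$; the posterior variance is
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and the moderated t
has $d_0 + d_g$ degrees of freedom. $d_0 = 0$ recovers the ordinary
t-test exactly (verified to 1e-8), and the degenerate all-equal-variance
input maps to $d_0 = \infty$ without overflow. Note the log-scale moment
map assumes chi-square spread in $s_g^2$; on a degenerate zero-spread
input $s_0^2$ is overstated by $\exp(\log(d_g/2) - \psi(d_g/2))$ (~11% at
$d_g = 10$), which is inherent to the estimator, not a defect.

## Rebound classification

Per contrast, DMPs are CpGs with nominal $p \le 0.05$ **and** an absolute
group-mean beta difference $> 0.05$ (direction from the beta-difference
sign; probes whose beta-difference and M-coefficient signs disagree —
possible near the beta boundaries — are excluded and counted). DEGs are
genes with nominal $p \le 0.05$. Both boundaries are deliberate: $p$ is
inclusive, $|\Delta\beta|$ exclusive. A feature *rebounds* when it is
significant in both the during-pregnancy (3rd−1st) and post-partum
(PP−3rd) windows with opposite directions; significance with the same
direction is reported separately as non-rebound overlap, and the two sets
exactly tile the significant-in-both set. The $|\Delta\beta|$ criterion is
applied in both windows (symmetry; the alternative single-window reading
is not adopted). *Shared* rebound features show the identical direction
pattern in both groups; per window the 2×2 direction-agreement
percentages are emitted as well. Shared rebound DMPs map to genes (DMGs)
as the union over the CpG→gene annotation, keeping multi-mapped genes.
The pre-pregnancy baseline check is available as
`incomplete_rebound_fraction()`: the fraction of rebound features whose
post-partum level still deviates from the baseline in the direction of the
3rd-trimester excursion.

## Network modules

The PPI network is a STRING-dialect edge list filtered at combined score
≥ 700, deduplicated and loop-free. Module expansion follows the DIAMOnD
seed-connector principle: at each iteration, each candidate node with
$k_s \ge 1$ links into the current module (size $s$, network size $N$,
node degree $k$) is scored by the hypergeometric tail
$P(X \ge k_s),\, X \sim \mathrm{Hyper}(N, s, k)$, and the smallest-$p$
node is added, up to 200 additions. Design choices:

* tails are computed in log space (`phyper(log.p = TRUE)`), so networks up
  to at least $N = 20{,}000$, $k = 2{,}000$ cannot underflow;
* ties on $p$ break towards the smaller degree, then the
  lexicographically smaller gene id — the expansion is fully
  deterministic (the original formulation leaves ties unspecified);
* the seed weight $\alpha$ defaults to 1 (unweighted); for $\alpha > 1$
  seed links and the seed contribution to module size count
  $\alpha$-fold;
* $N$ is the node count of the score-filtered network actually analyzed,
  not of any larger database;
* seeds absent from the network are dropped with a warning that lists
  them (never silently).

The expansion is validated against a brute-force oracle that re-derives
every candidate's tail probability by explicit summation each round; the
addition sequences agree exactly on batteries of random graphs. The
RNA-seq and methylation modules (seeded by shared rebound DEGs and DMGs
respectively) intersect into the rebound pregnancy module, with a Fisher
test of the overlap against the network node set; an induced subgraph at
score ≥ 950 is exported for rendering (no plotting is done in-package).

## Enrichment

`fisher_enrichment()` builds the 2×2 in-query × in-target table over an
explicit universe and tests it with the exact hypergeometric distribution,
one-sided ("greater") by default since enrichment is the reported
direction; the sample odds ratio $ad/bc$ is reported, with $bc = 0$
flagged as degenerate. Pathway enrichment over a GMT collection uses the
measured genes as background — united with the PPI node set when the query
is a module, which may contain network-only genes — and BH adjustment
across sets, reporting the gene ratio (overlap / query size). GWAS SNPs
with $p < 10^{-6}$ map to the gene with the nearest TSS; because
"nearest gene within a promoter window" is ambiguous in the upstream
tooling, the adopted rule is: nearest TSS by absolute distance,
strand-aware signed distance (upstream negative) must fall within
−3000..+3000, equidistant ties to the lexicographically smaller gene id,
and SNPs on chromosomes missing from the TSS table are skipped with a
count. BED inputs (0-based half-open) convert via `tss_from_bed()` to the
1-based TSS table.

The correlation-conservation analysis asks whether CpG–gene regulatory
coupling is preserved between groups: per group, the Spearman correlation
of each annotated CpG–gene pair across that group's paired samples
(pooled across timepoints within a cell type — the most inclusive reading,
since no restriction is stated), $|\rho|$ assigned to equal-count decile
bins within each group independently (rank-based, ties by first
occurrence), and per decile a 2×2 Fisher test of joint membership. Being
rank-based, the whole analysis is invariant to monotone transforms of
either omic.

## The synthetic-data generator

`generate_cohort()` emulates the study conditions: two donor groups
(defaults 11 disease, 7 control) sampled at BP/T1/T2/T3/PP with BP absent
in controls (`missing_pattern`), per-donor age and per-sample memory
fraction and viability with per-feature covariate slopes, a donor random
intercept inducing intra-donor correlation `rho_donor` (default 0.5), and
Gaussian M-value noise with total SD 0.5. A fraction `frac_rebound`
(default 0.02) of features carries a planted excursion of `effect_m` /
`effect_lfc` (default 2 on the M / log2 scale — free simulation
parameters, since the real effect magnitudes are unknown) that ramps up
through pregnancy (half at T2, full at T3) and collapses to 10% of itself
post-partum, making the reversal deliberately incomplete, in the same
direction in both groups. Counts are negative binomial (dispersion 0.1)
with the same design structure on the log2 mean and library sizes drawn
log-uniform over a 4-fold range, which keeps TMM/CPM non-trivial. A single
master seed derives independent sub-streams for the sample table,
methylation, counts and annotation, so runs are bitwise reproducible.
Planted CpGs annotate 1:1 onto planted genes so the two omics implicate a
common module; `generate_ppi()` plants a dense neighborhood (target
internal edge density) around those genes on a preferential-attachment
graph with scores in [700, 1000], and `generate_gene_sets()` builds a
disease set with an exact planted overlap fraction.

Deliberate simplifications, and what they mean for the tests: baseline
M-values are drawn N(0, 1) — the dynamic mid-methylated compartment —
rather than the bimodal near-0/near-1 distribution of real arrays, so
planted M-scale effects always produce detectable beta differences; there
is no probe chemistry, no read-level sequencing noise, no batch structure
beyond an additive covariate, and covariate slopes are Gaussian. Passing
recovery tests therefore demonstrates that the inference chain is correct
and calibrated under its own assumptions, not that real cohorts of this
size would yield comparable power — in particular, effects planted at
extreme baselines would be attenuated on the beta scale in real data. In
the activation companion generator, CD69+ fractions overlap between
resting and activated states (0.01–0.35 vs 0.30–0.95); with fully
separated ranges the state indicator and the continuous level covariate
would be collinear and the state effect unidentifiable — a property of the
design, not of the test.

## Numerical choices and degenerate inputs

* Beta clipping at `eps = 1e-6` bounds M-values at ±~19.9; round trips are
  exact to 1e-9 away from the clip.
* The CPM filter drops a gene when CPM < 10 in at least 70% of samples,
  evaluated with a 1e-9 slack against floating-point boundary artifacts;
  library sizes are pre-filter column sums; an all-zero sample is an
  error.
* TMM: reference = sample whose upper-quartile CPM is closest to the mean
  upper quartile; genes must be expressed in both libraries; inverse
  asymptotic binomial-variance weights; factors rescaled to geometric
  mean 1; a single sample yields unit factors with a warning. The
  implementation agrees with the established reference implementation to
  1e-10 on random count matrices.
* GLS whitening reuses one Cholesky factor of the equicorrelation matrix;
  per-feature weights enter as row scalings, so the weighted path costs
  one triangular solve per feature. A $\rho$ below
  $-1/(\max \text{block size} - 1)$ makes the covariance indefinite and is
  an explicit error.
* Zero-variance features get $t = 0, p = 1$ for a zero estimate rather
  than 0/0.
* All randomized validation uses fixed seeds; problem sizes were chosen as
  the smallest at which the asymptotic checks are stable: 10,000 features
  for null calibration, 5,000 for correlation recovery and the planted
  end-to-end scenario (20 replicate seeds), margins ≤ 30 for exhaustive
  2×2 enumeration.

## Known limitations

* The consensus-correlation estimator assumes a single exchangeable
  correlation shared by all features and all donor pairs; feature-specific
  or time-decaying correlation is out of scope (as are REML variance
  components and spline time trends).
* Variance moderation is plain (no robust or intensity-trend variant);
  the choice is deliberate, since nothing else is specified for this
  workflow.
* The beta-difference in DMP calling is a group-mean difference, not a
  paired within-donor mean — the unpaired reading of an ambiguous
  definition.
* BH adjustment is applied per contrast within omic and cell type,
  mirroring per-comparison reporting; no cross-contrast correction is
  attempted.
* Enrichment is overlap-based only; ranked (GSEA-style) analysis and
  ontology-topology handling are out of scope.
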