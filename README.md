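# reboundomics

Pregnancy transiently suppresses multiple sclerosis activity, with a
well-known post-partum worsening. In paired longitudinal CD4+/CD8+ T-cell
data, this shows up as a molecular **rebound**: methylation and expression
changes that build up to the 3rd trimester and reverse after delivery, in
patients and healthy controls alike. `reboundomics` is an R toolkit for
that inference chain, aimed at analysts working with longitudinal
multi-omics cohorts:

1. **Preprocessing** — probe QC filters, beta↔M transformation
   (M = log2 β/(1−β)), CPM-based low-count gene filtering, and
   trimmed-mean-of-M-values (TMM) normalization (implemented in-package,
   cross-checked against edgeR to 1e-10).
2. **Differential analysis** — per-feature generalized least squares for
   the model y = β₀ + β_{d,t}·s + β_a·a + β_m·m + β_c·c (group and time
   combined in one term; age, memory-cell fraction and viability as
   covariates), with a consensus intra-donor correlation, mean–variance
   precision weights for counts, and empirical-Bayes moderated
   t-statistics (prior df by trigamma inversion).
3. **Rebound classification** — DMPs (p ≤ 0.05 and |Δβ| > 0.05), DEGs
   (p ≤ 0.05), features reversing direction between the 3rd−1st and
   PP−3rd windows, and the *shared rebound* sets with identical patterns
   in both groups; CpG→gene mapping to DMGs.
4. **Network modules** — DIAMOnD seed-connector expansion on a STRING-style
   PPI network (score ≥ 700), scored by log-space hypergeometric
   connectivity p-values with deterministic tie-breaking; cross-omics
   module intersection and a score ≥ 950 visualization export.
5. **Enrichment** — exact Fisher/hypergeometric tests with explicit
   background rules, GMT pathway enrichment with BH correction, GWAS
   SNP→nearest-TSS gene mapping (±3 kb, strand-aware), and a CpG–gene
   Spearman correlation-conservation test by deciles.
6. **Synthetic cohorts** — a generator planting known rebound features,
   a dense PPI neighborhood and an overlapping disease gene set, so the
   whole pipeline is validated by parameter recovery.

See `vignettes/rebound-multiomics-methods.Rmd` for the model details and
every design decision.

## Worked example

The `analysis/` scripts run the whole study on a synthetic cohort shaped
like the real one (11 MS + 7 control donors over BP/T1/T2/T3/PP, no BP in
controls; 5,000 CpGs and genes with 2% planted rebound at effect 2 on the
M/log2 scale):

```sh
Rscript analysis/01_simulate.R --seed 1
Rscript analysis/02_differential.R
Rscript analysis/03_rebound.R
Rscript analysis/04_modules_enrichment.R
```

which prints (stage 2–4 excerpts):

```
consensus intra-donor correlation: 0.489 (methylation), 0.170 (expression)
MS T3-T1: 333 CpGs and 368 genes at p <= 0.05
...
MS: 118 rebound DMPs, 151 rebound DEGs; window correlation r = -0.88 (meth), -0.77 (expr)
HC: 127 rebound DMPs, 159 rebound DEGs; window correlation r = -0.84 (meth), -0.75 (expr)
shared rebound: 100 DMPs -> 100 DMGs, 98 DEGs
modules: 298 genes (RNA), 300 genes (methylation); intersection 264 genes
rebound module vs disease set: overlap 50, OR = 21.90, p = 1.4e-38
```

Reading this: the generator planted a donor correlation of 0.5 (recovered
as 0.489 on M-values; counts carry extra sampling noise, so their log-CPM
correlation is genuinely lower), 100 rebound CpGs and 100 rebound genes
(98–100 recovered as shared rebound; the per-group excess over 100
reflects the nominal-significance false-positive rate), strongly negative
during/after-pregnancy contrast correlations (the rebound signature), and
a cross-omics module significantly enriched for the planted disease set.
All tables land under `results/` (per-contrast statistics, rebound and
shared-rebound sets, direction-agreement quadrants, module membership with
iteration ranks and connectivity p-values, the ≥950 edge export, and
enrichment tables).

Equivalently in one call from R:

```r
library(reboundomics)
coh <- generate_cohort(cohort_config(seed = 1))
ppi <- generate_ppi(rownames(coh$counts), coh$truth$planted_module_genes,
                    extra_density = 0.3, seed = 2)
sets <- generate_gene_sets(rownames(coh$counts),
                           coh$truth$planted_module_genes, seed = 3)
res <- run_pipeline(pipeline_config(
  coh$beta, coh$counts, coh$samples, coh$annotation, ppi,
  gene_sets = sets, disease_set = "disease_set", out_dir = "results/run"))
res$manifest$stages
```

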