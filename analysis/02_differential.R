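#!/usr/bin/env Rscript

# Stage 2: preprocessing and moderated differential analysis.
#
# Methylation is tested on M-values; expression counts pass the CPM >= 10
# in >30% of samples filter, TMM normalization and precision weighting.
# Both omics share one design (intercept + one indicator per group-time
# cell with the 1st trimester as reference + age, memory fraction,
# viability), a consensus intra-donor correlation absorbed by GLS, and
# empirical-Bayes variance moderation. Per-contrast tables are written
# under results/differential/.

suppressPackageStartupMessages(library(reboundomics))

inp <- "results/inputs"
out <- "results/differential"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

beta <- read_omics_tsv(file.path(inp, "beta.tsv"), "beta")
counts <- read_omics_tsv(file.path(inp, "counts.tsv"), "count")
samples <- read_sample_tsv(file.path(inp, "samples.tsv"))

design <- build_design(samples, reference_time = "T1")
m_vals <- beta_m_transform(beta, "m")
counts_f <- filter_low_count_genes(counts)
nf <- tmm_factors(counts_f)
lcpm <- log_cpm(counts_f, nf)
w <- voom_weights(counts_f, design, nf)

rho_m <- as.numeric(estimate_block_correlation(m_vals, design))
rho_e <- as.numeric(estimate_block_correlation(lcpm, design))
fits_m <- fit_feature_models(m_vals, design, rho = rho_m)
fits_e <- fit_feature_models(lcpm, design, rho = rho_e, weights = w)
mod_m <- ebayes_moderate(fits_m)
mod_e <- ebayes_moderate(fits_e)

cat(sprintf("CPM filter: %d/%d genes retained\n", nrow(counts_f),
            nrow(counts)))
cat(sprintf("consensus intra-donor correlation: %.3f (methylation), %.3f (expression)\n",
            rho_m, rho_e))
cat(sprintf("variance prior df: %.1f / %.1f\n", mod_m$d0, mod_e$d0))

windows <- list(w1 = c("T3", "T1"), w2 = c("PP", "T3"))
for (g in c("MS", "HC")) {
  for (wn in names(windows)) {
    wdef <- windows[[wn]]
    cv <- time_contrast(design, g, wdef[1], wdef[2])
    res_m <- test_contrast(fits_m, mod_m, cv)
    res_m$delta_beta <- unname(
      mean_beta_difference(beta, samples, g, wdef[2], wdef[1]))
    res_e <- test_contrast(fits_e, mod_e, cv)
    utils::write.table(res_m, file.path(out, sprintf("meth_%s_%s.tsv", g, wn)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res_e, file.path(out, sprintf("expr_%s_%s.tsv", g, wn)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("%s %s-%s: %d CpGs and %d genes at p <= 0.05\n",
                g, wdef[1], wdef[2], sum(res_m$p <= 0.05),
                sum(res_e$p <= 0.05)))
  }
}
cat(sprintf("contrast tables written to %s/\n", out))
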