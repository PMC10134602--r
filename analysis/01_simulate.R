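#!/usr/bin/env Rscript

# Stage 1: simulate the study inputs.
#
# Builds a synthetic two-group longitudinal cohort shaped like the real
# study (11 disease / 7 control donors; BP,T1,T2,T3,PP with no BP samples
# in controls), with 2% of CpGs/genes carrying a planted rebound (an
# M-scale / log2 excursion of 2 at the 3rd trimester that reverses
# post-partum), plus a scored PPI network with a dense neighborhood around
# the planted genes and a gene-set collection whose "disease" set overlaps
# them by 50%. Everything is written under results/inputs/ in the plain
# formats the pipeline consumes.

suppressPackageStartupMessages(library(reboundomics))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1L

out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(n_cpgs = 5000L, n_genes = 5000L, seed = seed)
coh <- generate_cohort(cfg)
ppi <- generate_ppi(rownames(coh$counts),
                    planted = coh$truth$planted_module_genes,
                    extra_density = 0.3, seed = seed + 1L)
sets <- generate_gene_sets(rownames(coh$counts),
                           coh$truth$planted_module_genes,
                           overlap_frac = 0.5, seed = seed + 2L)

write_omics_tsv(coh$beta, file.path(out, "beta.tsv"))
write_omics_tsv(coh$counts, file.path(out, "counts.tsv"))
write_sample_tsv(coh$samples, file.path(out, "samples.tsv"))
write_sample_tsv(coh$annotation, file.path(out, "annotation.tsv"))
write_string_edges(ppi, file.path(out, "ppi_edges.txt"))
write_gmt(sets, file.path(out, "gene_sets.gmt"))
write_truth_json(coh$truth, file.path(out, "truth.json"))

cat(sprintf(
  "simulated %d samples (%d donors), %d CpGs, %d genes; planted %d rebound CpGs and %d rebound genes\n",
  nrow(coh$samples), length(unique(coh$samples$donor)), nrow(coh$beta),
  nrow(coh$counts), length(coh$truth$rebound_cpgs),
  length(coh$truth$rebound_genes)))
cat(sprintf("PPI: %d nodes, %d edges (scores 700-1000); %d gene sets\n",
            igraph::vcount(ppi), igraph::ecount(ppi), length(sets)))
cat(sprintf("inputs written to %s/\n", out))
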