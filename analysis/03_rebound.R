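#!/usr/bin/env Rscript

# Stage 3: rebound classification.
#
# DMPs (p <= 0.05 and |delta beta| > 0.05) and DEGs (p <= 0.05) are called
# per group for the during-pregnancy (3rd-1st) and post-partum (PP-3rd)
# windows; features significant in both windows with opposite directions
# are rebound features, and those with the identical pattern in both
# groups form the shared rebound sets. Shared rebound DMPs map to genes
# (DMGs) through the CpG annotation. Genome-wide window correlations
# quantify the reversal.

suppressPackageStartupMessages(library(reboundomics))

inp <- "results/inputs"
dif <- "results/differential"
out <- "results/rebound"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

annotation <- read_sample_tsv(file.path(inp, "annotation.tsv"))
read_res <- function(f) {
  structure(utils::read.delim(file.path(dif, f), stringsAsFactors = FALSE),
            class = c("differential_result", "data.frame"))
}

rebound <- list()
for (g in c("MS", "HC")) {
  m1 <- read_res(sprintf("meth_%s_w1.tsv", g))
  m2 <- read_res(sprintf("meth_%s_w2.tsv", g))
  e1 <- read_res(sprintf("expr_%s_w1.tsv", g))
  e2 <- read_res(sprintf("expr_%s_w2.tsv", g))
  rebound[[paste0(g, "_meth")]] <- find_rebound(call_dmps(m1), call_dmps(m2))
  rebound[[paste0(g, "_expr")]] <- find_rebound(call_degs(e1), call_degs(e2))
  cc_m <- contrast_correlation(m1, m2)
  cc_e <- contrast_correlation(e1, e2)
  cat(sprintf(
    "%s: %d rebound DMPs, %d rebound DEGs; window correlation r = %.2f (meth), %.2f (expr)\n",
    g, nrow(rebound[[paste0(g, "_meth")]]$rebound),
    nrow(rebound[[paste0(g, "_expr")]]$rebound), cc_m$r, cc_e$r))
  for (om in c("meth", "expr")) {
    utils::write.table(rebound[[paste0(g, "_", om)]]$rebound,
                       file.path(out, sprintf("rebound_%s_%s.tsv", g, om)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
}

shared_m <- shared_rebound(rebound$MS_meth, rebound$HC_meth)
shared_e <- shared_rebound(rebound$MS_expr, rebound$HC_expr)
dmgs <- map_cpgs_to_genes(shared_m$shared$feature, annotation)
cat(sprintf("shared rebound: %d DMPs -> %d DMGs, %d DEGs\n",
            nrow(shared_m$shared), length(dmgs), nrow(shared_e$shared)))

utils::write.table(shared_m$shared, file.path(out, "shared_rebound_dmps.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(shared_e$shared, file.path(out, "shared_rebound_degs.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(dmgs, file.path(out, "shared_rebound_dmgs.txt"))
for (om in c("meth", "expr")) {
  q <- if (om == "meth") shared_m$quadrants else shared_e$quadrants
  for (wn in names(q)) {
    utils::write.table(as.data.frame(q[[wn]]),
                       file.path(out, sprintf("quadrants_%s_%s.tsv", om, wn)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
}
cat(sprintf("rebound tables written to %s/\n", out))
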