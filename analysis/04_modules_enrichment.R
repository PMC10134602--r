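#!/usr/bin/env Rscript

# Stage 4: network modules and enrichment.
#
# The shared rebound DEGs (expression) and DMGs (methylation) seed DIAMOnD
# expansion on the score >= 700 PPI network (200 genes added per omic);
# the intersection of the two modules is the rebound pregnancy module. The
# module is tested for enrichment in the disease gene set (one-sided
# Fisher over measured + network genes) and against the full gene-set
# collection with BH correction; the score >= 950 induced subgraph is
# exported for rendering.

suppressPackageStartupMessages(library(reboundomics))

inp <- "results/inputs"
reb <- "results/rebound"
out <- "results/modules"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ppi <- load_ppi(file.path(inp, "ppi_edges.txt"), min_score = 700)
sets <- read_gmt(file.path(inp, "gene_sets.gmt"))
counts <- read_omics_tsv(file.path(inp, "counts.tsv"), "count")
annotation <- read_sample_tsv(file.path(inp, "annotation.tsv"))
seeds_e <- utils::read.delim(file.path(reb, "shared_rebound_degs.tsv"))$feature
seeds_m <- read_gene_list(file.path(reb, "shared_rebound_dmgs.txt"))

mod_rna <- diamond_expand(ppi, seeds_e, n_added = 200)
mod_meth <- diamond_expand(ppi, seeds_m, n_added = 200)
net_nodes <- igraph::V(ppi)$name
inter <- intersect_modules(mod_rna, mod_meth, net_nodes)
cat(sprintf(
  "modules: %d genes (RNA), %d genes (methylation); intersection %d genes (overlap OR %.1f, p %.2g)\n",
  length(mod_rna$module), length(mod_meth$module), length(inter$genes),
  inter$enrichment$odds_ratio, inter$enrichment$p))

write_module_tsv(mod_rna, file.path(out, "module_rna.tsv"))
write_module_tsv(mod_meth, file.path(out, "module_meth.tsv"))
writeLines(inter$genes, file.path(out, "rebound_module_genes.txt"))
viz <- export_viz_subgraph(ppi, inter$genes, min_score = 950,
                           file = file.path(out, "viz_edges.tsv"))
cat(sprintf("visualization subgraph (score >= 950): %d edges\n", nrow(viz)))

measured <- union(rownames(counts), unique(annotation$gene))
disease <- fisher_enrichment(inter$genes, sets$disease_set,
                             union(measured, net_nodes))
cat(sprintf("rebound module vs disease set: overlap %d, OR = %.2f, p = %.2g\n",
            disease$overlap, disease$odds_ratio, disease$p))
utils::write.table(disease, file.path(out, "disease_enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

paths <- pathway_enrichment(inter$genes, sets, measured, net_nodes,
                            "measured_plus_network")
cat(sprintf("pathway enrichment: %d/%d sets significant at adjusted p <= 0.05\n",
            sum(paths$significant), nrow(paths)))
utils::write.table(paths, file.path(out, "pathway_enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("module tables written to %s/\n", out))
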