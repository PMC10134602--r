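#' Pipeline configuration
#'
#' Bundles the inputs and every tunable threshold of the end-to-end
#' analysis. Matrix/table inputs may be in-memory objects or file paths
#' (TSV for matrices and tables, STRING dialect for the PPI, GMT for gene
#' sets); paths are loaded at run time.
#'
#' @param beta beta [omics_matrix()] or TSV path.
#' @param counts count [omics_matrix()] or TSV path.
#' @param samples sample table or TSV path.
#' @param annotation CpG-gene annotation (columns cpg, gene) or TSV path.
#' @param ppi igraph or STRING edge-list path.
#' @param gene_sets named list of gene sets, GMT path, or NULL.
#' @param disease_set gene vector (or name of an element of `gene_sets`)
#'   tested for enrichment in the rebound module; NULL to skip.
#' @param groups the two group labels, disease first.
#' @param covariates numeric covariates absorbed in the design.
#' @param reference_time baseline timepoint.
#' @param window1,window2 the two contrast windows as c(later, earlier);
#'   defaults: 3rd trimester vs 1st, post-partum vs 3rd.
#' @param p_max nominal p threshold for DMPs/DEGs.
#' @param db_min absolute beta-difference threshold for DMPs.
#' @param ppi_min_score minimal combined score retained in the PPI.
#' @param n_added DIAMOnD expansion size.
#' @param cpm_min,cpm_frac low-count gene filter parameters.
#' @param viz_score score threshold of the exported visualization subgraph.
#' @param pathway_adj_max adjusted-p threshold for pathway calls.
#' @param out_dir output directory (NULL: no files written).
#' @param seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(beta, counts, samples, annotation, ppi,
                            gene_sets = NULL, disease_set = NULL,
                            groups = c("MS", "HC"),
                            covariates = c("age", "memory", "viability"),
                            reference_time = "T1",
                            window1 = c("T3", "T1"),
                            window2 = c("PP", "T3"),
                            p_max = 0.05, db_min = 0.05,
                            ppi_min_score = 700, n_added = 200,
                            cpm_min = 10, cpm_frac = 0.7, viz_score = 950,
                            pathway_adj_max = 0.05, out_dir = NULL,
                            seed = 1L) {
  stopifnot(p_max > 0, p_max <= 1, db_min >= 0, ppi_min_score >= 0,
            n_added >= 0, cpm_min >= 0, cpm_frac >= 0, cpm_frac <= 1,
            pathway_adj_max > 0, pathway_adj_max <= 1,
            length(groups) == 2)
  cfg <- as.list(environment())
  for (el in c("beta", "counts", "samples", "annotation", "ppi",
               "gene_sets")) {
    v <- cfg[[el]]
    if (is.character(v) && length(v) == 1 && !file.exists(v)) {
      stop(sprintf("input file for `%s` does not exist: %s", el, v),
           call. = FALSE)
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [pipeline_config()]; matrix and
#' table inputs are given as file paths.
#' @param file YAML path.
#' @export
pipeline_config_yaml <- function(file) {
  args <- yaml::read_yaml(file)
  for (nm in c("groups", "covariates", "window1", "window2",
               "disease_set")) {
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  do.call(pipeline_config, args)
}

resolve_inputs <- function(cfg) {
  if (is.character(cfg$beta)) cfg$beta <- read_omics_tsv(cfg$beta, "beta")
  if (is.character(cfg$counts)) cfg$counts <- read_omics_tsv(cfg$counts,
                                                             "count")
  if (is.character(cfg$samples)) cfg$samples <- read_sample_tsv(cfg$samples)
  if (is.character(cfg$annotation)) {
    cfg$annotation <- read_sample_tsv(cfg$annotation)
  }
  if (is.character(cfg$ppi)) {
    cfg$ppi <- load_ppi(cfg$ppi, cfg$ppi_min_score)
  } else {
    keep <- igraph::E(cfg$ppi)$combined_score >= cfg$ppi_min_score
    cfg$ppi <- igraph::subgraph_from_edges(cfg$ppi, igraph::E(cfg$ppi)[keep],
                                           delete.vertices = FALSE)
  }
  if (is.character(cfg$gene_sets)) cfg$gene_sets <- read_gmt(cfg$gene_sets)
  if (is.character(cfg$disease_set) && length(cfg$disease_set) == 1 &&
      !is.null(cfg$gene_sets) && cfg$disease_set %in% names(cfg$gene_sets)) {
    cfg$disease_set <- cfg$gene_sets[[cfg$disease_set]]
  }
  cfg
}

#' Run the end-to-end rebound pipeline
#'
#' Preprocessing (low-count filter, TMM, logCPM, M-values), moderated
#' differential analysis for both omics over the two contrast windows in
#' both groups, rebound and shared-rebound classification, CpG-to-gene
#' mapping, DIAMOnD expansion of the shared rebound genes per omic,
#' cross-omics module intersection, and enrichment of the intersection
#' module in the disease gene set plus pathway enrichment. All stage
#' outputs, per-stage counts and parameters are collected in a manifest;
#' with `out_dir` set, tables and the JSON manifest are also written.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with elements `differential`,
#'   `calls`, `rebound`, `shared`, `correlations`, `modules`, `enrichment`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- resolve_inputs(config)
  log_lines <- character()
  say <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage_counts <- list()
  g1 <- cfg$groups[1]; g2 <- cfg$groups[2]
  w1 <- cfg$window1; w2 <- cfg$window2

  ## preprocess ----------------------------------------------------------
  m_vals <- beta_m_transform(cfg$beta, "m")
  counts_f <- filter_low_count_genes(cfg$counts, cfg$cpm_min, cfg$cpm_frac)
  nf <- tmm_factors(counts_f)
  lcpm <- log_cpm(counts_f, nf)
  stage_counts$preprocess <- list(
    n_cpgs = nrow(cfg$beta), n_genes_in = nrow(cfg$counts),
    n_genes_kept = nrow(counts_f))
  say("preprocess", "%d CpGs; %d/%d genes pass the CPM filter",
      nrow(cfg$beta), nrow(counts_f), nrow(cfg$counts))

  ## differential --------------------------------------------------------
  design <- build_design(cfg$samples, cfg$covariates, cfg$reference_time)
  rho_m <- as.numeric(estimate_block_correlation(m_vals, design))
  fits_m <- fit_feature_models(m_vals, design, rho = rho_m)
  mod_m <- ebayes_moderate(fits_m)
  w <- voom_weights(counts_f, design, nf)
  rho_e <- as.numeric(estimate_block_correlation(lcpm, design))
  fits_e <- fit_feature_models(lcpm, design, rho = rho_e, weights = w)
  mod_e <- ebayes_moderate(fits_e)
  contrasts <- list()
  for (g in c(g1, g2)) {
    contrasts[[paste0(g, "_w1")]] <- time_contrast(design, g, w1[1], w1[2])
    contrasts[[paste0(g, "_w2")]] <- time_contrast(design, g, w2[1], w2[2])
  }
  diff_m <- lapply(contrasts, function(cv) {
    test_contrast(fits_m, mod_m, cv)
  })
  diff_e <- lapply(contrasts, function(cv) {
    test_contrast(fits_e, mod_e, cv)
  })
  say("differential", "rho_meth=%.3f rho_expr=%.3f d0_meth=%.1f d0_expr=%.1f",
      rho_m, rho_e, mod_m$d0, mod_e$d0)

  ## rebound -------------------------------------------------------------
  calls_m <- list(); calls_e <- list(); rebound <- list()
  for (g in c(g1, g2)) {
    db1 <- mean_beta_difference(cfg$beta, cfg$samples, g, w1[2], w1[1])
    db2 <- mean_beta_difference(cfg$beta, cfg$samples, g, w2[2], w2[1])
    calls_m[[paste0(g, "_w1")]] <- call_dmps(diff_m[[paste0(g, "_w1")]],
                                             db1, cfg$p_max, cfg$db_min)
    calls_m[[paste0(g, "_w2")]] <- call_dmps(diff_m[[paste0(g, "_w2")]],
                                             db2, cfg$p_max, cfg$db_min)
    calls_e[[paste0(g, "_w1")]] <- call_degs(diff_e[[paste0(g, "_w1")]],
                                             cfg$p_max)
    calls_e[[paste0(g, "_w2")]] <- call_degs(diff_e[[paste0(g, "_w2")]],
                                             cfg$p_max)
    rebound[[paste0(g, "_meth")]] <- find_rebound(
      calls_m[[paste0(g, "_w1")]], calls_m[[paste0(g, "_w2")]])
    rebound[[paste0(g, "_expr")]] <- find_rebound(
      calls_e[[paste0(g, "_w1")]], calls_e[[paste0(g, "_w2")]])
  }
  shared_m <- shared_rebound(rebound[[paste0(g1, "_meth")]],
                             rebound[[paste0(g2, "_meth")]])
  shared_e <- shared_rebound(rebound[[paste0(g1, "_expr")]],
                             rebound[[paste0(g2, "_expr")]])
  dmgs <- map_cpgs_to_genes(shared_m$shared$feature, cfg$annotation)
  stage_counts$rebound <- list(
    rebound_dmps = stats::setNames(
      lapply(c(g1, g2), function(g) nrow(rebound[[paste0(g, "_meth")]]$rebound)),
      c(g1, g2)),
    rebound_degs = stats::setNames(
      lapply(c(g1, g2), function(g) nrow(rebound[[paste0(g, "_expr")]]$rebound)),
      c(g1, g2)),
    shared_rebound_dmps = nrow(shared_m$shared),
    shared_rebound_degs = nrow(shared_e$shared),
    shared_rebound_dmgs = length(dmgs))
  say("rebound", "shared rebound: %d DMPs -> %d DMGs; %d DEGs",
      nrow(shared_m$shared), length(dmgs), nrow(shared_e$shared))

  ## genome-wide contrast correlations -----------------------------------
  correlations <- list()
  for (g in c(g1, g2)) {
    correlations[[paste0(g, "_meth")]] <- contrast_correlation(
      diff_m[[paste0(g, "_w1")]], diff_m[[paste0(g, "_w2")]])
    correlations[[paste0(g, "_expr")]] <- contrast_correlation(
      diff_e[[paste0(g, "_w1")]], diff_e[[paste0(g, "_w2")]])
  }

  ## modules -------------------------------------------------------------
  seeds_e <- shared_e$shared$feature
  seeds_m <- dmgs
  modules <- NULL
  enrichment <- NULL
  net_nodes <- igraph::V(cfg$ppi)$name
  if (length(intersect(seeds_e, net_nodes)) == 0 ||
      length(intersect(seeds_m, net_nodes)) == 0) {
    stage_counts$modules <- list(skipped = TRUE,
                                 reason = "empty shared rebound seed set")
    say("modules", "skipped: empty shared rebound seed set")
  } else {
    mod_rna <- suppressWarnings(
      diamond_expand(cfg$ppi, seeds_e, cfg$n_added))
    mod_meth <- suppressWarnings(
      diamond_expand(cfg$ppi, seeds_m, cfg$n_added))
    inter <- intersect_modules(mod_rna, mod_meth, net_nodes)
    viz <- export_viz_subgraph(cfg$ppi, inter$genes, cfg$viz_score)
    modules <- list(rna = mod_rna, meth = mod_meth, intersection = inter,
                    viz_edges = viz)
    stage_counts$modules <- list(
      skipped = FALSE,
      n_module_rna = length(mod_rna$module),
      n_module_meth = length(mod_meth$module),
      n_intersection = length(inter$genes))
    say("modules", "RNA %d, methylation %d, intersection %d genes",
        length(mod_rna$module), length(mod_meth$module),
        length(inter$genes))

    ## enrichment --------------------------------------------------------
    measured <- union(rownames(counts_f), unique(cfg$annotation$gene))
    universe <- union(measured, net_nodes)
    enrichment <- list()
    if (!is.null(cfg$disease_set)) {
      enrichment$disease_module <- fisher_enrichment(
        inter$genes, cfg$disease_set, universe)
      enrichment$disease_seeds <- fisher_enrichment(
        union(seeds_e, seeds_m), cfg$disease_set, universe)
      say("enrichment", "module vs disease set: OR=%.2f p=%.3g",
          enrichment$disease_module$odds_ratio,
          enrichment$disease_module$p)
    }
    if (!is.null(cfg$gene_sets)) {
      enrichment$pathways <- pathway_enrichment(
        inter$genes, cfg$gene_sets, measured, net_nodes,
        "measured_plus_network", cfg$pathway_adj_max)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("reboundomics")),
    seed = cfg$seed,
    parameters = cfg[c("p_max", "db_min", "ppi_min_score", "n_added",
                       "cpm_min", "cpm_frac", "viz_score",
                       "pathway_adj_max", "reference_time", "groups",
                       "covariates")],
    stages = stage_counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  result <- structure(list(
    differential = list(meth = diff_m, expr = diff_e,
                        rho = c(meth = rho_m, expr = rho_e),
                        d0 = c(meth = mod_m$d0, expr = mod_e$d0)),
    calls = list(meth = calls_m, expr = calls_e),
    rebound = rebound,
    shared = list(meth = shared_m, expr = shared_e, dmgs = dmgs),
    correlations = correlations,
    modules = modules,
    enrichment = enrichment,
    manifest = manifest,
    log = log_lines), class = "pipeline_result")

  if (!is.null(cfg$out_dir)) write_pipeline_outputs(result, cfg)
  result
}

# persist stage tables, the manifest and the log under cfg$out_dir
write_pipeline_outputs <- function(result, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$out_dir, ...)
  for (nm in names(result$rebound)) {
    utils::write.table(result$rebound[[nm]]$rebound,
                       out(sprintf("rebound_%s.tsv", nm)), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(result$shared$meth$shared, out("shared_rebound_dmps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$shared$expr$shared, out("shared_rebound_degs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(result$shared$dmgs, out("shared_rebound_dmgs.txt"))
  # category counts feeding an alluvial rendering: per group, counts by
  # direction pattern across the two windows
  cats <- do.call(rbind, lapply(names(result$rebound), function(nm) {
    r <- result$rebound[[nm]]$rebound
    if (nrow(r) == 0) return(NULL)
    agg <- as.data.frame(table(pattern = r$pattern),
                         stringsAsFactors = FALSE)
    cbind(set = nm, agg)
  }))
  if (!is.null(cats)) {
    utils::write.table(cats, out("rebound_categories.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (om in c("meth", "expr")) {
    q <- result$shared[[om]]$quadrants
    for (wn in names(q)) {
      utils::write.table(as.data.frame(q[[wn]]),
                         out(sprintf("quadrants_%s_%s.tsv", om, wn)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(result$modules)) {
    write_module_tsv(result$modules$rna, out("module_rna.tsv"))
    write_module_tsv(result$modules$meth, out("module_meth.tsv"))
    writeLines(result$modules$intersection$genes,
               out("module_intersection.txt"))
    utils::write.table(result$modules$viz_edges, out("viz_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$enrichment$pathways)) {
    utils::write.table(result$enrichment$pathways,
                       out("pathway_enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(result$log, out("pipeline.log"))
  invisible(cfg$out_dir)
}
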