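#' Load a STRING-dialect PPI edge list
#'
#' Whitespace-separated file with a header and three columns (protein1,
#' protein2, combined_score). Edges below `min_score` are dropped,
#' symmetric duplicates collapse to a single undirected edge (keeping the
#' maximal score), and self-loops are removed.
#'
#' @param edge_file path.
#' @param min_score minimal combined score retained (inclusive).
#' @return igraph with edge attribute `combined_score`; attributes
#'   `n_nodes`, `n_edges` record the loaded sizes.
#' @export
load_ppi <- function(edge_file, min_score = 700) {
  lines <- readLines(edge_file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) stop("empty edge file", call. = FALSE)
  parts <- strsplit(trimws(lines[-1]), "[[:space:]]+")
  nf <- lengths(parts)
  if (any(nf != 3)) {
    stop(sprintf("malformed line %d: expected 3 whitespace-separated fields",
                 which(nf != 3)[1] + 1L), call. = FALSE)
  }
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, `[[`, character(1), 2L)
  s <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
  if (anyNA(s)) {
    stop(sprintf("malformed line %d: non-numeric combined_score",
                 which(is.na(s))[1] + 1L), call. = FALSE)
  }
  make_ppi_graph(data.frame(a = a, b = b, score = s,
                            stringsAsFactors = FALSE), min_score)
}

# shared constructor: score filter, self-loop removal, deduplication
make_ppi_graph <- function(edges, min_score) {
  edges <- edges[edges$score >= min_score & edges$a != edges$b, ,
                 drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::E(g)$combined_score <- edges$score
  g <- igraph::simplify(g, edge.attr.comb = list(combined_score = "max",
                                                 "ignore"))
  attr(g, "n_nodes") <- igraph::vcount(g)
  attr(g, "n_edges") <- igraph::ecount(g)
  g
}

# log-space hypergeometric upper tail P(X >= ks) for vectors of candidates
log_hyper_tail <- function(ks, k, s, N) {
  stats::phyper(ks - 1, s, N - s, k, lower.tail = FALSE, log.p = TRUE)
}

#' DIAMOnD seed-connector module expansion
#'
#' Iteratively grows a module from the seed genes: at each step every
#' candidate node with at least one link into the current module is scored
#' by the hypergeometric tail probability of having `k_s` or more of its
#' `k` links inside a module of size `s` in an `N`-node network, and the
#' node with the smallest probability is added. Links to seed genes and the
#' seed contribution to the module size are weighted by `alpha`
#' (`alpha = 1` is the plain algorithm). Probabilities are computed in log
#' space, so large networks do not underflow. Ties are broken towards the
#' smaller degree, then the lexicographically smaller gene id, making the
#' expansion deterministic.
#'
#' @param graph PPI igraph (vertex names = gene ids).
#' @param seeds seed gene ids; those absent from the graph are dropped with
#'   a warning.
#' @param n_added maximum number of genes to add.
#' @param alpha integer seed weight (>= 1).
#' @return list of class `module_result`: `seeds` (in-graph),
#'   `seeds_missing`, `added` (data.frame gene, iteration, k, k_s, p),
#'   `module` (seeds plus added, in addition order).
#' @export
diamond_expand <- function(graph, seeds, n_added = 200, alpha = 1) {
  stopifnot(alpha >= 1, alpha == round(alpha))
  nodes <- igraph::V(graph)$name
  present <- intersect(seeds, nodes)
  missing <- setdiff(seeds, nodes)
  if (length(present) == 0) {
    stop("none of the seed genes are present in the graph", call. = FALSE)
  }
  if (length(missing)) {
    warning(sprintf("%d seed gene(s) absent from the graph: %s",
                    length(missing),
                    paste(utils::head(missing, 10), collapse = ", ")))
  }
  N <- length(nodes)
  adj <- igraph::as_adj_list(graph)
  names(adj) <- nodes
  neighbors <- lapply(adj, function(vs) nodes[as.integer(vs)])
  degree <- stats::setNames(lengths(neighbors), nodes)

  in_module <- stats::setNames(rep(FALSE, N), nodes)
  in_module[present] <- TRUE
  is_seed <- stats::setNames(rep(FALSE, N), nodes)
  is_seed[present] <- TRUE

  # per-candidate links into module, split seed / non-seed
  ks_seed <- stats::setNames(integer(N), nodes)
  ks_other <- stats::setNames(integer(N), nodes)
  for (s in present) {
    nb <- neighbors[[s]]
    ks_seed[nb] <- ks_seed[nb] + 1L
  }
  n_seeds_in <- length(present)
  n_other_in <- 0L
  added <- vector("list", n_added)
  i <- 0L
  while (i < n_added) {
    cand <- nodes[!in_module & (ks_seed + ks_other) > 0L]
    if (length(cand) == 0) break
    ks_eff <- alpha * ks_seed[cand] + ks_other[cand]
    k_eff <- degree[cand] + (alpha - 1L) * ks_seed[cand]
    s_eff <- alpha * n_seeds_in + n_other_in
    N_eff <- N + (alpha - 1L) * n_seeds_in
    logp <- log_hyper_tail(ks_eff, k_eff, s_eff, N_eff)
    ord <- order(logp, degree[cand], cand)
    best <- cand[ord[1]]
    i <- i + 1L
    added[[i]] <- data.frame(
      gene = best, iteration = i, k = unname(degree[best]),
      k_s = unname(ks_seed[best] + ks_other[best]),
      p = exp(logp[ord[1]]), log_p = logp[ord[1]],
      stringsAsFactors = FALSE)
    in_module[best] <- TRUE
    n_other_in <- n_other_in + 1L
    nb <- neighbors[[best]]
    ks_other[nb] <- ks_other[nb] + 1L
  }
  added_df <- if (i > 0) do.call(rbind, added[seq_len(i)]) else
    data.frame(gene = character(), iteration = integer(), k = integer(),
               k_s = integer(), p = numeric(), log_p = numeric())
  structure(list(seeds = present, seeds_missing = missing,
                 added = added_df,
                 module = c(present, added_df$gene)),
            class = "module_result")
}

#' Intersect modules across omics
#'
#' The genes common to the two final modules, with a one-sided Fisher test
#' of the overlap against the network's node set as universe.
#'
#' @param module_a,module_b `module_result`s (or plain gene vectors).
#' @param universe gene universe (e.g. the PPI node set).
#' @return list: `genes`, `enrichment` (an [fisher_enrichment()] row).
#' @export
intersect_modules <- function(module_a, module_b, universe) {
  ga <- if (inherits(module_a, "module_result")) module_a$module else module_a
  gb <- if (inherits(module_b, "module_result")) module_b$module else module_b
  ga <- intersect(ga, universe); gb <- intersect(gb, universe)
  common <- sort(intersect(ga, gb))
  enr <- fisher_enrichment(ga, gb, universe)
  list(genes = common, enrichment = enr)
}

#' Export the high-confidence visualization subgraph
#'
#' The induced subgraph on `genes`, keeping only edges with combined score
#' at least `min_score` (default 950, the high-stringency cut used for
#' rendering), as a plain edge list.
#'
#' @param graph PPI igraph with `combined_score` edge attribute.
#' @param genes gene ids (subset of the graph's namespace).
#' @param min_score minimal score retained (inclusive).
#' @param file optional TSV output path.
#' @return data.frame: gene_a, gene_b, score.
#' @export
export_viz_subgraph <- function(graph, genes, min_score = 950, file = NULL) {
  sub <- igraph::induced_subgraph(graph,
                                  intersect(genes, igraph::V(graph)$name))
  keep <- igraph::E(sub)$combined_score >= min_score
  el <- igraph::as_edgelist(sub)
  out <- data.frame(gene_a = el[keep, 1], gene_b = el[keep, 2],
                    score = igraph::E(sub)$combined_score[keep],
                    stringsAsFactors = FALSE)
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' Write a module result as TSV
#' @param module a `module_result`.
#' @param file path.
#' @export
write_module_tsv <- function(module, file) {
  seed_df <- data.frame(gene = module$seeds, origin = "seed",
                        iteration = NA_integer_, k = NA_integer_,
                        k_s = NA_integer_, p = NA_real_,
                        stringsAsFactors = FALSE)
  add_df <- module$added[, c("gene", "iteration", "k", "k_s", "p")]
  if (nrow(add_df)) add_df <- cbind(gene = add_df$gene, origin = "added",
                                    add_df[, -1, drop = FALSE])
  out <- rbind(seed_df, if (nrow(module$added)) add_df)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
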