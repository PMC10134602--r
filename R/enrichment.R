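#' Fisher enrichment of a query gene set in a target set
#'
#' Builds the 2x2 table (in-query x in-target over the universe) and tests
#' it with the exact hypergeometric distribution. The default alternative
#' is one-sided enrichment ("greater"); "two.sided" sums all tables at most
#' as probable as the observed one. The odds ratio is the sample odds ratio
#' `ad/bc`; when `bc = 0` it is reported as `Inf` with `or_degenerate =
#' TRUE`.
#'
#' @param query,target gene sets (subsets of `universe`).
#' @param universe background gene set.
#' @param alternative "greater", "less" or "two.sided".
#' @return one-row data.frame: overlap, n_query, n_target, n_universe,
#'   odds_ratio, or_degenerate, p.
#' @export
fisher_enrichment <- function(query, target, universe,
                              alternative = c("greater", "less",
                                              "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  target <- intersect(unique(target), universe)
  a <- length(intersect(query, target))
  b <- length(query) - a
  cc <- length(target) - a
  d <- length(universe) - a - b - cc
  p <- hyper_test_p(a, b, cc, d, alternative)
  degenerate <- (b * cc) == 0
  or <- if (degenerate) {
    if (a * d == 0) 0 else Inf
  } else (a * d) / (b * cc)
  if (a == 0) or <- 0
  data.frame(overlap = a, n_query = length(query), n_target = length(target),
             n_universe = length(universe), odds_ratio = or,
             or_degenerate = degenerate, p = p,
             stringsAsFactors = FALSE)
}

# exact p for the 2x2 table with fixed margins
hyper_test_p <- function(a, b, cc, d, alternative) {
  m <- a + cc          # target size
  n <- b + d           # non-target size
  k <- a + b           # query size
  switch(alternative,
    greater = stats::phyper(a - 1, m, n, k, lower.tail = FALSE),
    less = stats::phyper(a, m, n, k),
    two.sided = {
      support <- max(0, k - n):min(k, m)
      dens <- stats::dhyper(support, m, n, k)
      sum(dens[dens <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
    })
}

#' Pathway enrichment of a query gene set over a GMT collection
#'
#' One-sided hypergeometric test per set with Benjamini-Hochberg adjustment
#' across sets. The background is either the measured genes alone or the
#' measured genes united with the network's node set (the rule applied when
#' testing module genes, which may contain network-only genes).
#'
#' @param query gene set.
#' @param genesets named list of gene sets (e.g. [read_gmt()]).
#' @param measured measured gene universe.
#' @param network_genes network node set (used by
#'   `universe_mode = "measured_plus_network"`).
#' @param universe_mode background rule.
#' @param p_adj_max adjusted-p threshold for the `significant` flag.
#' @return data.frame: set, overlap, n_set, n_query, n_universe, gene_ratio,
#'   odds_ratio, p, adj_p, significant.
#' @export
pathway_enrichment <- function(query, genesets, measured,
                               network_genes = character(),
                               universe_mode = c("measured",
                                                 "measured_plus_network"),
                               p_adj_max = 0.05) {
  universe_mode <- match.arg(universe_mode)
  universe <- unique(measured)
  if (universe_mode == "measured_plus_network") {
    universe <- unique(c(universe, network_genes))
  }
  query <- intersect(unique(query), universe)
  if (length(query) == 0) {
    stop("empty query after universe intersection", call. = FALSE)
  }
  rows <- lapply(names(genesets), function(nm) {
    res <- fisher_enrichment(query, genesets[[nm]], universe)
    data.frame(set = nm, overlap = res$overlap, n_set = res$n_target,
               n_query = res$n_query, n_universe = res$n_universe,
               gene_ratio = res$overlap / res$n_query,
               odds_ratio = res$odds_ratio, p = res$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p, "BH")
  out$significant <- out$adj_p <= p_adj_max
  out[order(out$p), , drop = FALSE]
}

#' Map GWAS SNPs to genes by nearest TSS
#'
#' Filters SNPs to `p < p_max` and assigns each to the gene with the
#' nearest transcription start site, using the strand-aware signed distance
#' (upstream of the TSS is negative). Only assignments whose signed
#' distance falls inside `window` are kept; equidistant ties go to the
#' lexicographically smaller gene id. SNPs on chromosomes absent from the
#' TSS table are skipped and counted.
#'
#' @param snps data.frame: id, chrom, pos (1-based), p.
#' @param tss data.frame: gene, chrom, tss_pos (1-based), strand
#'   ("+"/"-").
#' @param p_max GWAS significance threshold (exclusive).
#' @param window allowed signed distance range around the TSS.
#' @return sorted gene vector; attributes `n_snps_used`,
#'   `n_skipped_chrom`, `n_outside_window`.
#' @export
gwas_snps_to_genes <- function(snps, tss, p_max = 1e-6,
                               window = c(-3000, 3000)) {
  stopifnot(all(c("id", "chrom", "pos", "p") %in% names(snps)),
            all(c("gene", "chrom", "tss_pos", "strand") %in% names(tss)),
            nrow(tss) > 0)
  use <- snps[snps$p < p_max, , drop = FALSE]
  skipped <- sum(!use$chrom %in% tss$chrom)
  genes <- character(0)
  outside <- 0L
  for (ch in intersect(unique(use$chrom), unique(tss$chrom))) {
    tch <- tss[tss$chrom == ch, , drop = FALSE]
    tch <- tch[order(tch$tss_pos, tch$gene), , drop = FALSE]
    for (pos in use$pos[use$chrom == ch]) {
      dist <- abs(pos - tch$tss_pos)
      near <- which(dist == min(dist))          # ordered: ties prefer
      hit <- tch[near[1], ]                     # smaller gene id at same pos
      if (length(near) > 1) {
        cand <- tch[near, ]
        hit <- cand[order(cand$gene)[1], ]
      }
      signed <- (pos - hit$tss_pos) * ifelse(hit$strand == "-", -1, 1)
      if (signed >= window[1] && signed <= window[2]) {
        genes <- c(genes, hit$gene)
      } else {
        outside <- outside + 1L
      }
    }
  }
  structure(sort(unique(genes)), n_snps_used = nrow(use),
            n_skipped_chrom = skipped, n_outside_window = outside)
}

#' CpG-gene correlation conservation between groups
#'
#' For each annotated CpG-gene pair measured in both omics, the Spearman
#' correlation across a group's paired samples quantifies the regulation
#' the CpG exerts on its gene. Absolute correlations are binned into
#' deciles within each group independently, and each decile is tested for
#' conserved membership across the two groups with a 2x2 Fisher test over
#' all pairs.
#'
#' @param meth beta or M [omics_matrix()].
#' @param expr logCPM (or count) [omics_matrix()].
#' @param annotation data.frame: cpg, gene.
#' @param samples sample table; samples present in both matrices are used,
#'   pooled across timepoints within each group.
#' @param groups the two group labels to compare (default: the first two in
#'   the sample table).
#' @param n_bins number of bins (default deciles).
#' @return list: `pairs` (per-pair correlations and bins per group),
#'   `tests` (per-bin data.frame: bin, overlap, odds_ratio, p).
#' @export
correlation_conservation <- function(meth, expr, annotation, samples,
                                     groups = NULL, n_bins = 10) {
  if (is.null(groups)) groups <- unique(samples$group)[1:2]
  stopifnot(length(groups) == 2)
  pairs <- annotation[annotation$cpg %in% rownames(meth) &
                        annotation$gene %in% rownames(expr), , drop = FALSE]
  pairs <- unique(pairs[, c("cpg", "gene")])
  if (nrow(pairs) == 0) stop("no measurable CpG-gene pairs", call. = FALSE)
  bin_of <- list()
  cors <- list()
  for (g in groups) {
    ids <- samples$sample[samples$group == g]
    ids <- intersect(intersect(ids, colnames(meth)), colnames(expr))
    if (length(ids) < 4) {
      stop(sprintf("fewer than 4 paired samples in group %s", g),
           call. = FALSE)
    }
    mv <- om_values(meth)[pairs$cpg, ids, drop = FALSE]
    ev <- om_values(expr)[pairs$gene, ids, drop = FALSE]
    # row-wise Spearman: correlate ranks
    mr <- t(apply(mv, 1, rank))
    er <- t(apply(ev, 1, rank))
    mr <- mr - rowMeans(mr); er <- er - rowMeans(er)
    rho <- rowSums(mr * er) /
      sqrt(rowSums(mr^2) * rowSums(er^2))
    rho[!is.finite(rho)] <- 0
    # equal-count decile bins on |rho| (rank-based, ties by first occurrence)
    bin_of[[g]] <- ceiling(rank(abs(rho), ties.method = "first") *
                             n_bins / length(rho))
    cors[[g]] <- unname(rho)
  }
  tests <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    in1 <- bin_of[[groups[1]]] == b
    in2 <- bin_of[[groups[2]]] == b
    a <- sum(in1 & in2); bb <- sum(in1 & !in2)
    cc <- sum(!in1 & in2); d <- sum(!in1 & !in2)
    data.frame(bin = b, overlap = a,
               odds_ratio = if (bb * cc == 0) {
                 if (a * d == 0) 0 else Inf
               } else (a * d) / (bb * cc),
               p = hyper_test_p(a, bb, cc, d, "greater"))
  }))
  list(pairs = data.frame(cpg = pairs$cpg, gene = pairs$gene,
                          rho_1 = cors[[groups[1]]],
                          rho_2 = cors[[groups[2]]],
                          bin_1 = bin_of[[groups[1]]],
                          bin_2 = bin_of[[groups[2]]],
                          stringsAsFactors = FALSE),
       tests = tests)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone and bounded by 1.
#' @param pvals numeric vector in [0, 1].
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}
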