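test_that("Fisher enrichment reproduces the textbook 2x2 computation", {
  universe <- sprintf("g%04d", 1:1000)
  query <- universe[1:20]                 # a = 10, b = 10
  target <- universe[c(1:10, 21:30)]      # c = 10, d = 970
  res <- fisher_enrichment(query, target, universe)
  expect_equal(res$overlap, 10)
  expect_equal(res$odds_ratio, (10 * 970) / (10 * 10))   # 97
  # brute-force tail over the hypergeometric support
  expect_equal(res$p, oracle_hyper_tail(10, 20, 20, 1000),
               tolerance = 1e-12)
  # agreement with the exact conditional test in stats::fisher.test
  ref <- fisher.test(matrix(c(10, 10, 10, 970), 2), alternative = "greater")
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  two <- fisher_enrichment(query, target, universe,
                           alternative = "two.sided")
  ref2 <- fisher.test(matrix(c(10, 10, 10, 970), 2))
  expect_equal(two$p, ref2$p.value, tolerance = 1e-8)
  # degenerate conventions
  empty <- fisher_enrichment(query, character(), universe)
  expect_equal(empty$overlap, 0)
  expect_equal(empty$odds_ratio, 0)
  expect_equal(empty$p, 1)
  expect_error(fisher_enrichment(query, target, character()), "universe")
})

test_that("pathway enrichment ranks the exactly-matching set first and is
           calibrated under a random query", {
  set.seed(55)
  universe <- sprintf("g%04d", 1:2000)
  sets <- c(list(hit_set = universe[1:100]),
            lapply(setNames(1:50, sprintf("rand%02d", 1:50)),
                   function(i) sample(universe, 80)))
  res <- pathway_enrichment(universe[1:100], sets, measured = universe)
  expect_identical(res$set[1], "hit_set")
  expect_equal(res$gene_ratio[1], 1)
  # a uniformly random query flags (essentially) nothing
  res0 <- pathway_enrichment(sample(universe, 100), sets[-1],
                             measured = universe)
  expect_lte(sum(res0$significant), 1)
  # widening the background can only grow the universe
  resN <- pathway_enrichment(universe[1:100], sets, measured = universe,
                             network_genes = sprintf("n%03d", 1:500),
                             universe_mode = "measured_plus_network")
  expect_gte(resN$n_universe[1], res$n_universe[1])
  expect_error(pathway_enrichment("absent", sets, measured = universe),
               "empty query")
})

test_that("GWAS SNPs map to the nearest TSS with strand-aware windowing", {
  tss <- data.frame(gene = c("A", "B", "C"),
                    chrom = c("chr1", "chr1", "chr2"),
                    tss_pos = c(1000L, 9000L, 5000L),
                    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  snps <- data.frame(
    id = sprintf("rs%d", 1:6),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr3", "chr1"),
    pos = c(1000L, 2500L, 8000L, 5100L, 100L, 5000L),
    p = c(rep(1e-8, 5), 0.5), stringsAsFactors = FALSE)
  g <- gwas_snps_to_genes(snps, tss, p_max = 1e-6, window = c(-3000, 3000))
  # rs1 exact TSS -> A; rs2 within +3kb of A; rs3 1kb from B (upstream on -);
  # rs4 near C; rs5 chr3 skipped; rs6 fails the GWAS threshold
  expect_identical(as.character(g), c("A", "B", "C"))
  expect_identical(attr(g, "n_skipped_chrom"), 1L)
  expect_identical(attr(g, "n_snps_used"), 5L)
  # equidistant tie goes to the lexicographically smaller gene id
  snps_tie <- data.frame(id = "rs9", chrom = "chr1", pos = 5000L, p = 1e-8)
  expect_identical(as.character(gwas_snps_to_genes(snps_tie, tss)),
                   character(0))   # 4kb away: outside the +-3kb window
  tss_close <- data.frame(gene = c("Z", "Y"), chrom = "chr1",
                          tss_pos = c(4000L, 6000L), strand = "+",
                          stringsAsFactors = FALSE)
  expect_identical(as.character(gwas_snps_to_genes(snps_tie, tss_close)),
                   "Y")
  # strand-aware sign: 1kb downstream of a minus-strand TSS is negative
  tss_minus <- data.frame(gene = "M", chrom = "chr1", tss_pos = 1000L,
                          strand = "-", stringsAsFactors = FALSE)
  snp_up <- data.frame(id = "rs10", chrom = "chr1", pos = 3500L, p = 1e-8)
  g2 <- gwas_snps_to_genes(snp_up, tss_minus)   # signed -2500: inside
  expect_identical(as.character(g2), "M")
})

test_that("correlation conservation: identical groups give maximal decile
           overlap and the test is invariant to monotone transforms", {
  set.seed(66)
  n_pairs <- 200
  cpgs <- sprintf("cg%04d", 1:n_pairs)
  genes <- sprintf("g%04d", 1:n_pairs)
  ann <- data.frame(cpg = cpgs, gene = genes, stringsAsFactors = FALSE)
  mk_samples <- function() {
    data.frame(sample = sprintf("s%02d", 1:20), donor = sprintf("d%02d", 1:20),
               group = rep(c("MS", "HC"), each = 10),
               timepoint = "T1", stringsAsFactors = FALSE)
  }
  s <- mk_samples()
  mv <- matrix(runif(n_pairs * 20, 0.05, 0.95), n_pairs,
               dimnames = list(cpgs, s$sample))
  ev <- matrix(rnorm(n_pairs * 20, 5, 2), n_pairs,
               dimnames = list(genes, s$sample))
  # make group HC a copy of group MS
  mv[, 11:20] <- mv[, 1:10]; ev[, 11:20] <- ev[, 1:10]
  res <- correlation_conservation(omics_matrix(mv, "beta"),
                                  omics_matrix(ev, "logcpm"), ann, s)
  expect_true(all(res$pairs$bin_1 == res$pairs$bin_2))
  expect_true(all(res$tests$overlap == 20))
  expect_true(all(res$tests$p < 1e-6))
  # Spearman invariance: monotone transform of either omic changes nothing
  res2 <- correlation_conservation(omics_matrix(mv^3, "beta"),
                                   omics_matrix(exp(ev), "logcpm"), ann, s)
  expect_equal(res$pairs$rho_1, res2$pairs$rho_1, tolerance = 1e-12)
  expect_identical(res$tests, res2$tests)
  expect_error(
    correlation_conservation(omics_matrix(mv[, 1:12], "beta"),
                             omics_matrix(ev[, 1:12], "logcpm"), ann,
                             s[1:12, ]), "4 paired")
})

test_that("independent groups give near-unit decile odds ratios", {
  set.seed(67)
  n_pairs <- 5000
  cpgs <- sprintf("cg%05d", 1:n_pairs)
  genes <- sprintf("g%05d", 1:n_pairs)
  ann <- data.frame(cpg = cpgs, gene = genes, stringsAsFactors = FALSE)
  s <- data.frame(sample = sprintf("s%02d", 1:24),
                  donor = sprintf("d%02d", 1:24),
                  group = rep(c("MS", "HC"), each = 12), timepoint = "T1",
                  stringsAsFactors = FALSE)
  mv <- matrix(runif(n_pairs * 24), n_pairs, dimnames = list(cpgs, s$sample))
  ev <- matrix(rnorm(n_pairs * 24), n_pairs, dimnames = list(genes, s$sample))
  res <- correlation_conservation(omics_matrix(mv, "beta"),
                                  omics_matrix(ev, "logcpm"), ann, s)
  expect_gte(median(res$tests$odds_ratio), 0.8)
  expect_lte(median(res$tests$odds_ratio), 1.25)
})

test_that("decile assignment follows the manual ranking on a small fixture", {
  set.seed(68)
  n <- 20
  cpgs <- sprintf("cg%02d", 1:n); genes <- sprintf("g%02d", 1:n)
  ann <- data.frame(cpg = cpgs, gene = genes, stringsAsFactors = FALSE)
  s <- data.frame(sample = sprintf("s%02d", 1:10),
                  donor = sprintf("d%02d", 1:10),
                  group = rep(c("MS", "HC"), each = 5), timepoint = "T1",
                  stringsAsFactors = FALSE)
  mv <- matrix(runif(n * 10), n, dimnames = list(cpgs, s$sample))
  ev <- matrix(rnorm(n * 10), n, dimnames = list(genes, s$sample))
  res <- correlation_conservation(omics_matrix(mv, "beta"),
                                  omics_matrix(ev, "logcpm"), ann, s,
                                  n_bins = 10)
  # manual Spearman per pair in group MS
  manual <- vapply(seq_len(n), function(i) {
    cor(mv[i, 1:5], ev[i, 1:5], method = "spearman")
  }, numeric(1))
  expect_equal(res$pairs$rho_1, manual, tolerance = 1e-12)
  manual_bins <- ceiling(rank(abs(manual), ties.method = "first") * 10 / n)
  expect_identical(res$pairs$bin_1, manual_bins)
})

test_that("BH adjustment matches the longhand step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(69)
  for (i in 1:5) {
    p <- runif(200)
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12 & adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})
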