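# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: tail probabilities by explicit summation,
# step-up adjustment written out longhand, GLS by direct normal equations.

# hypergeometric upper tail P(X >= ks), X ~ Hyper(N, s, k), by summation
oracle_hyper_tail <- function(ks, k, s, N) {
  lo <- max(ks, 0)
  hi <- min(k, s)
  if (lo > hi) return(0)
  sum(exp(lchoose(s, lo:hi) + lchoose(N - s, k - (lo:hi)) - lchoose(N, k)))
}

# brute-force DIAMOnD: recompute every candidate's tail each round
oracle_diamond <- function(graph, seeds, n_added) {
  nodes <- igraph::V(graph)$name
  N <- length(nodes)
  nb <- lapply(igraph::as_adj_list(graph), function(v) nodes[as.integer(v)])
  names(nb) <- nodes
  module <- intersect(seeds, nodes)
  added <- character()
  for (i in seq_len(n_added)) {
    cand <- setdiff(nodes, module)
    cand <- cand[vapply(cand, function(v) any(nb[[v]] %in% module),
                        logical(1))]
    if (length(cand) == 0) break
    stats <- t(vapply(cand, function(v) {
      k <- length(nb[[v]])
      ks <- sum(nb[[v]] %in% module)
      c(k = k, ks = ks,
        p = oracle_hyper_tail(ks, k, length(module), N))
    }, c(k = 0, ks = 0, p = 0)))
    ord <- order(stats[, "p"], stats[, "k"], cand)
    best <- cand[ord[1]]
    module <- c(module, best)
    added <- c(added, best)
  }
  added
}

# longhand Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# direct GLS solve from the normal equations
oracle_gls <- function(y, X, Sigma) {
  Si <- solve(Sigma)
  A <- solve(t(X) %*% Si %*% X)
  list(coef = drop(A %*% t(X) %*% Si %*% y), cov_unscaled = A)
}

# small balanced cohort for unit tests (no BP, balanced groups)
small_cohort <- function(n_donors = 4L, n_cpgs = 200L, n_genes = 200L,
                         frac_rebound = 0.05, seed = 42L, ...) {
  cohort_config(
    n_donors_per_group = c(MS = n_donors, HC = n_donors),
    timepoints = c("T1", "T2", "T3", "PP"), n_cpgs = n_cpgs,
    n_genes = n_genes, frac_rebound = frac_rebound,
    missing_pattern = list(), seed = seed, ...)
}

# random connected-ish test graph with combined scores
random_scored_graph <- function(n, p_edge, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p_edge)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("G%03d", seq_len(n))
  igraph::E(g)$combined_score <- sample(700:1000, igraph::ecount(g),
                                        replace = TRUE)
  g
}
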