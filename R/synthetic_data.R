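#' Cohort simulation configuration
#'
#' Defines a two-group longitudinal cohort sampled at up to five ordered
#' timepoints (pre-pregnancy BP, trimesters T1-T3, post-partum PP). Defaults
#' mirror a small pregnancy cohort: 11 disease (MS) and 7 control (HC)
#' donors, all five timepoints with BP unavailable in HC. A configurable
#' fraction of features carries a planted "rebound": a shift of `effect_m`
#' (M-value scale) / `effect_lfc` (log2 expression) at T3 relative to T1
#' that reverses after delivery, identically directed in both groups. The
#' reversal is deliberately incomplete: planted features retain 10% of the
#' T3 excursion at PP, so post-partum values approach but do not reach the
#' pre-pregnancy baseline.
#'
#' @param n_donors_per_group named integer vector, donors per group.
#' @param timepoints ordered subset of `c("BP","T1","T2","T3","PP")`.
#' @param n_cpgs,n_genes number of methylation / expression features.
#' @param frac_rebound fraction of features with a planted rebound, in [0,1].
#' @param effect_m planted T3 effect on the M-value scale (log2-odds units).
#' @param effect_lfc planted T3 log2 fold-change for expression.
#' @param rho_donor intra-donor correlation of repeated measures, in [0,1).
#' @param dispersion negative-binomial dispersion (>= 0) for counts.
#' @param sigma_m total M-value residual SD (donor + sample components).
#' @param sigma_g total log2-expression biological SD entering the NB mean.
#' @param covariate_effects named numeric: SDs of per-feature slopes for
#'   `age` (per year), `memory` (per unit memory-cell fraction) and
#'   `viability` (per unit viability), on the M/log2 scale.
#' @param missing_pattern named list: per group, timepoints to omit
#'   (default: BP absent in HC).
#' @param seed master RNG seed; all sub-streams derive from it.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_donors_per_group = c(MS = 11L, HC = 7L),
                          timepoints = c("BP", "T1", "T2", "T3", "PP"),
                          n_cpgs = 5000L,
                          n_genes = 5000L,
                          frac_rebound = 0.02,
                          effect_m = 2,
                          effect_lfc = 2,
                          rho_donor = 0.5,
                          dispersion = 0.1,
                          sigma_m = 0.5,
                          sigma_g = 0.4,
                          covariate_effects = c(age = 0.02, memory = 1,
                                                viability = 0.2),
                          missing_pattern = list(HC = "BP"),
                          seed = 1L) {
  tp_order <- c("BP", "T1", "T2", "T3", "PP")
  fail <- function(field, msg) {
    stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  if (length(n_donors_per_group) < 1 || is.null(names(n_donors_per_group)) ||
      any(n_donors_per_group < 1)) {
    fail("n_donors_per_group", "must be a named vector of positive integers")
  }
  if (anyDuplicated(timepoints) || !all(timepoints %in% tp_order)) {
    fail("timepoints", "must be a unique subset of BP,T1,T2,T3,PP")
  }
  timepoints <- tp_order[tp_order %in% timepoints]
  if (n_cpgs < 10 || n_genes < 10) {
    fail(if (n_cpgs < 10) "n_cpgs" else "n_genes", "must be >= 10")
  }
  if (frac_rebound < 0 || frac_rebound > 1) {
    fail("frac_rebound", "must lie in [0, 1]")
  }
  if (rho_donor < 0 || rho_donor >= 1) fail("rho_donor", "must lie in [0, 1)")
  if (dispersion < 0) fail("dispersion", "must be >= 0")
  if (sigma_m <= 0) fail("sigma_m", "must be > 0")
  req <- c("age", "memory", "viability")
  if (!all(req %in% names(covariate_effects))) {
    fail("covariate_effects", "must name age, memory and viability")
  }
  if (!all(names(missing_pattern) %in% names(n_donors_per_group))) {
    fail("missing_pattern", "names must be group labels")
  }
  structure(list(
    n_donors_per_group = as.integer(n_donors_per_group) |>
      stats::setNames(names(n_donors_per_group)),
    timepoints = timepoints, n_cpgs = as.integer(n_cpgs),
    n_genes = as.integer(n_genes), frac_rebound = frac_rebound,
    effect_m = effect_m, effect_lfc = effect_lfc, rho_donor = rho_donor,
    dispersion = dispersion, sigma_m = sigma_m, sigma_g = sigma_g,
    covariate_effects = covariate_effects, missing_pattern = missing_pattern,
    seed = as.integer(seed)), class = "cohort_config")
}

# Fraction of the planted T3 excursion still present at PP ("the rebound
# is not complete"): PP sits 10% of the way back towards T3.
PP_RESIDUAL_FRAC <- 0.1
# Ramp of the planted effect over pregnancy: builds to a maximum at T3.
TIME_RAMP <- c(BP = 0, T1 = 0, T2 = 0.5, T3 = 1, PP = PP_RESIDUAL_FRAC)

# Deterministic sub-seeds (< 2^31) derived from the master seed, so each
# generated artifact has its own independent stream.
derive_subseeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a synthetic longitudinal cohort with planted rebound features
#'
#' Methylation is simulated on the M-value scale as a per-CpG baseline plus
#' planted group/time effects, per-feature covariate terms, a donor random
#' intercept (variance `rho_donor * sigma_m^2`) and Gaussian noise, then
#' transformed to beta values. Counts are negative binomial with the same
#' design structure on the log2 mean and library sizes drawn log-uniform
#' over a 4-fold range. Planted features shift by +/- effect at T3 versus T1
#' and reverse at PP, in the same direction in both groups.
#'
#' @param config a [cohort_config()].
#' @return list with elements `beta` and `counts` ([omics_matrix()]s),
#'   `samples` (data.frame: sample, donor, group, timepoint, cell_type,
#'   state, age, memory, viability, batch), `annotation` (data.frame:
#'   cpg, gene), and `truth` (list: rebound_cpgs, rebound_genes,
#'   planted_module_genes, cpg_effects, gene_effects, direction vectors).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ss <- derive_subseeds(config$seed, 4L)
  samples <- sim_sample_table(config, ss[1])
  n_reb_cpg <- round(config$frac_rebound * config$n_cpgs)
  n_reb_gene <- round(config$frac_rebound * config$n_genes)

  set.seed(ss[2])
  cpg_ids <- sprintf("cg%07d", seq_len(config$n_cpgs))
  gene_ids <- sprintf("GENE%05d", seq_len(config$n_genes))
  rebound_cpgs <- if (n_reb_cpg > 0) sort(sample(cpg_ids, n_reb_cpg)) else character()
  rebound_genes <- if (n_reb_gene > 0) sort(sample(gene_ids, n_reb_gene)) else character()

  beta <- sim_methylation(config, samples, cpg_ids, rebound_cpgs)
  set.seed(ss[3])
  counts <- sim_counts(config, samples, gene_ids, rebound_genes)
  set.seed(ss[4])
  annotation <- sim_annotation(cpg_ids, gene_ids, rebound_cpgs, rebound_genes)

  truth <- list(
    rebound_cpgs = rebound_cpgs,
    rebound_genes = rebound_genes,
    planted_module_genes = rebound_genes,
    cpg_effects = attr(beta, "true_effect"),
    gene_effects = attr(counts, "true_effect"),
    cpg_direction = attr(beta, "true_direction"),
    gene_direction = attr(counts, "true_direction"))
  attr(beta, "true_effect") <- NULL; attr(beta, "true_direction") <- NULL
  attr(counts, "true_effect") <- NULL; attr(counts, "true_direction") <- NULL
  list(beta = beta, counts = counts, samples = samples,
       annotation = annotation, truth = truth)
}

sim_sample_table <- function(config, seed) {
  set.seed(seed)
  rows <- list()
  for (g in names(config$n_donors_per_group)) {
    tps <- setdiff(config$timepoints, config$missing_pattern[[g]])
    for (d in seq_len(config$n_donors_per_group[[g]])) {
      donor <- sprintf("%s%02d", g, d)
      age <- round(stats::rnorm(1, 33, 4), 1)
      for (tp in tps) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sprintf("%s_%s", donor, tp), donor = donor, group = g,
          timepoint = tp, cell_type = "CD4", state = "resting", age = age,
          memory = round(stats::runif(1, 0.3, 0.7), 3),
          viability = round(stats::runif(1, 0.7, 0.99), 3),
          batch = sprintf("b%d", (d %% 2L) + 1L),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# design-structured linear predictor shared by both omics (on M / log2 scale)
sim_signal <- function(config, samples, ids, planted, effect) {
  n <- length(ids); ns <- nrow(samples)
  is_planted <- ids %in% planted
  # planted direction: half +1 (hyper/up at T3), half -1; deterministic split
  dir <- numeric(n)
  if (any(is_planted)) {
    k <- which(is_planted)
    dir[k] <- rep(c(1, -1), length.out = length(k))
  }
  ramp <- TIME_RAMP[samples$timepoint]
  eff_mat <- (dir * effect) %o% ramp          # features x samples
  ce <- config$covariate_effects
  slope_age <- stats::rnorm(n, 0, ce[["age"]])
  slope_mem <- stats::rnorm(n, 0, ce[["memory"]])
  slope_via <- stats::rnorm(n, 0, ce[["viability"]])
  cov_mat <- slope_age %o% (samples$age - 33) +
    slope_mem %o% (samples$memory - 0.5) +
    slope_via %o% (samples$viability - 0.85)
  list(signal = eff_mat + cov_mat, direction = dir,
       effect = dir * effect)
}

sim_methylation <- function(config, samples, cpg_ids, rebound_cpgs) {
  n <- config$n_cpgs; ns <- nrow(samples)
  baseline <- stats::rnorm(n, 0, 1)           # mid-methylated compartment
  sig <- sim_signal(config, samples, cpg_ids, rebound_cpgs, config$effect_m)
  sd_u <- sqrt(config$rho_donor) * config$sigma_m
  sd_e <- sqrt(1 - config$rho_donor) * config$sigma_m
  donors <- unique(samples$donor)
  u <- matrix(stats::rnorm(n * length(donors), 0, sd_u), n,
              dimnames = list(NULL, donors))
  m <- baseline + sig$signal + u[, samples$donor, drop = FALSE] +
    matrix(stats::rnorm(n * ns, 0, sd_e), n)
  dimnames(m) <- list(cpg_ids, samples$sample)
  beta <- omics_matrix(2^m / (1 + 2^m), "beta")
  attr(beta, "true_effect") <- stats::setNames(sig$effect, cpg_ids)
  attr(beta, "true_direction") <- stats::setNames(sig$direction, cpg_ids)
  beta
}

sim_counts <- function(config, samples, gene_ids, rebound_genes) {
  n <- config$n_genes; ns <- nrow(samples)
  base_expr <- stats::rnorm(n, 5, 1.5)        # relative log2 abundance
  sig <- sim_signal(config, samples, gene_ids, rebound_genes,
                    config$effect_lfc)
  sd_u <- sqrt(config$rho_donor) * config$sigma_g
  sd_e <- sqrt(1 - config$rho_donor) * config$sigma_g
  donors <- unique(samples$donor)
  u <- matrix(stats::rnorm(n * length(donors), 0, sd_u), n,
              dimnames = list(NULL, donors))
  log2q <- base_expr + sig$signal + u[, samples$donor, drop = FALSE] +
    matrix(stats::rnorm(n * ns, 0, sd_e), n)
  q <- 2^log2q
  # library sizes: log-uniform over a 4-fold range
  lib <- round(exp(stats::runif(ns, log(2.5e5), log(1e6))))
  mu <- sweep(q, 2, lib / colSums(q), `*`)
  size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
  cnt <- matrix(
    if (is.finite(size)) stats::rnbinom(n * ns, mu = mu, size = size)
    else stats::rpois(n * ns, lambda = mu), n)
  dimnames(cnt) <- list(gene_ids, samples$sample)
  counts <- omics_matrix(cnt, "count")
  attr(counts, "true_effect") <- stats::setNames(sig$effect, gene_ids)
  attr(counts, "true_direction") <- stats::setNames(sig$direction, gene_ids)
  counts
}

# CpG -> gene annotation; planted rebound CpGs map 1:1 (recycled) onto the
# planted rebound genes so methylation and expression modules cohere; ~5% of
# null CpGs are unannotated and ~5% map to two genes.
sim_annotation <- function(cpg_ids, gene_ids, rebound_cpgs, rebound_genes) {
  rows <- list()
  nulls <- setdiff(cpg_ids, rebound_cpgs)
  if (length(rebound_cpgs)) {
    g <- if (length(rebound_genes)) {
      rep(rebound_genes, length.out = length(rebound_cpgs))
    } else {
      sample(gene_ids, length(rebound_cpgs), replace = TRUE)
    }
    rows[[1]] <- data.frame(cpg = rebound_cpgs, gene = g,
                            stringsAsFactors = FALSE)
  }
  r <- stats::runif(length(nulls))
  annotated <- nulls[r >= 0.05]
  rows[[length(rows) + 1L]] <- data.frame(
    cpg = annotated, gene = sample(gene_ids, length(annotated), replace = TRUE),
    stringsAsFactors = FALSE)
  second <- nulls[r >= 0.95]
  if (length(second)) {
    rows[[length(rows) + 1L]] <- data.frame(
      cpg = second, gene = sample(gene_ids, length(second), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  out <- unique(do.call(rbind, rows))
  out[order(out$cpg, out$gene), , drop = FALSE]
}

#' Generate a synthetic PPI network with a planted dense neighborhood
#'
#' A preferential-attachment (Barabasi-Albert) graph over the gene universe,
#' with extra edges added among the planted genes until their internal edge
#' density reaches `extra_density`. Every edge carries an integer combined
#' score in [700, 1000], mimicking a score-filtered STRING export.
#'
#' @param genes integer (number of genes; ids are generated) or character
#'   vector of gene identifiers.
#' @param planted gene ids forming the dense neighborhood; must be a subset
#'   of the universe.
#' @param attach_m edges added per node during preferential attachment.
#' @param extra_density target internal edge density of `planted`, in [0,1].
#' @param seed RNG seed.
#' @return an [igraph::igraph] with vertex names and edge attribute
#'   `combined_score`.
#' @export
generate_ppi <- function(genes, planted = character(), attach_m = 3L,
                         extra_density = 0, seed = 1L) {
  ids <- if (is.numeric(genes) && length(genes) == 1) {
    sprintf("GENE%05d", seq_len(genes))
  } else as.character(genes)
  if (!all(planted %in% ids)) {
    stop("`planted` must be a subset of the gene universe", call. = FALSE)
  }
  if (attach_m < 1) stop("`attach_m` must be >= 1", call. = FALSE)
  if (extra_density > 0 && length(planted) < 2) {
    stop("`extra_density` > 0 requires at least 2 planted genes",
         call. = FALSE)
  }
  set.seed(seed)
  g <- igraph::sample_pa(length(ids), m = attach_m, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sample(ids)            # detach ids from hub order
  if (length(planted) >= 2 && extra_density > 0) {
    need <- ceiling(extra_density * choose(length(planted), 2))
    pairs <- t(utils::combn(planted, 2))
    present <- igraph::get_edge_ids(g, t(pairs)) > 0
    have <- sum(present)
    if (have < need) {
      absent <- pairs[!present, , drop = FALSE]
      add <- absent[sample.int(nrow(absent), need - have), , drop = FALSE]
      g <- igraph::add_edges(g, as.vector(t(add)))
    }
  }
  igraph::E(g)$combined_score <- sample(700:1000, igraph::ecount(g),
                                        replace = TRUE)
  g
}

#' Generate synthetic gene sets with one disease set overlapping the
#' planted genes
#'
#' @param universe gene identifiers.
#' @param planted gene ids (subset of `universe`).
#' @param n_sets total number of sets (the first is the disease set).
#' @param overlap_frac fraction of `planted` included in the disease set.
#' @param set_size size of every set (disease set grows if needed).
#' @param seed RNG seed.
#' @return named list of character vectors; first element `"disease_set"`.
#' @export
generate_gene_sets <- function(universe, planted = character(), n_sets = 20L,
                               overlap_frac = 0.5, set_size = 100L,
                               seed = 1L) {
  if (!all(planted %in% universe)) {
    stop("`planted` must be a subset of `universe`", call. = FALSE)
  }
  if (overlap_frac < 0 || overlap_frac > 1) {
    stop("invalid `overlap_frac`: must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  n_in <- round(overlap_frac * length(planted))
  core <- if (n_in > 0) sample(planted, n_in) else character()
  fillers <- sample(setdiff(universe, planted),
                    max(set_size - n_in, 0))
  sets <- list(disease_set = sort(unique(c(core, fillers))))
  if (n_sets > 1) {
    for (i in 2:n_sets) {
      sets[[sprintf("set_%02d", i)]] <-
        sort(sample(universe, min(set_size, length(universe))))
    }
  }
  sets
}

#' Write a PPI graph as a STRING-dialect edge list
#'
#' Three whitespace-separated columns with a header line:
#' `protein1 protein2 combined_score`.
#' @param graph igraph with vertex names and `combined_score` edge attribute.
#' @param file path.
#' @export
write_string_edges <- function(graph, file) {
  el <- igraph::as_edgelist(graph)
  df <- data.frame(protein1 = el[, 1], protein2 = el[, 2],
                   combined_score = igraph::E(graph)$combined_score)
  utils::write.table(df, file, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write the cohort ground truth as JSON
#' @param truth the `truth` element of [generate_cohort()].
#' @param file path.
#' @export
write_truth_json <- function(truth, file) {
  jsonlite::write_json(truth, file, auto_unbox = FALSE, digits = NA)
  invisible(file)
}

#' Generate a resting/activated expression cohort with planted
#' activation-responsive genes
#'
#' Companion generator for the in vitro activation contrast: `n_per_state`
#' independent samples per state, a per-sample activation level (fraction of
#' CD69+ cells, higher when activated), and `n_affected` genes shifted by
#' `lfc` in activated samples.
#'
#' @param n_per_state samples per state (resting, activated).
#' @param n_genes number of genes.
#' @param n_affected number of activation-responsive genes.
#' @param lfc planted log2 fold-change (activated vs resting).
#' @param dispersion negative-binomial dispersion.
#' @param seed RNG seed.
#' @return list(counts, samples, truth) with `truth$affected_genes`.
#' @export
generate_activation_cohort <- function(n_per_state = 20L, n_genes = 2000L,
                                       n_affected = 100L, lfc = 2,
                                       dispersion = 0.1, seed = 1L) {
  set.seed(seed)
  ns <- 2L * n_per_state
  gene_ids <- sprintf("GENE%05d", seq_len(n_genes))
  state <- rep(c("resting", "activated"), each = n_per_state)
  # CD69+ fractions overlap between states so the state indicator and the
  # continuous level are jointly identifiable in the design
  act_level <- ifelse(state == "activated", stats::runif(ns, 0.3, 0.95),
                      stats::runif(ns, 0.01, 0.35))
  samples <- data.frame(
    sample = sprintf("S%03d", seq_len(ns)), donor = sprintf("D%03d", seq_len(ns)),
    group = "HC", state = state, activation_level = round(act_level, 3),
    stringsAsFactors = FALSE)
  affected <- if (n_affected > 0) sort(sample(gene_ids, n_affected)) else character()
  dir <- stats::setNames(numeric(n_genes), gene_ids)
  dir[affected] <- rep(c(1, -1), length.out = length(affected))
  base_expr <- stats::rnorm(n_genes, 5, 1.5)
  log2q <- base_expr + (dir * lfc) %o% as.numeric(state == "activated") +
    matrix(stats::rnorm(n_genes * ns, 0, 0.3), n_genes)
  q <- 2^log2q
  lib <- round(exp(stats::runif(ns, log(2.5e5), log(1e6))))
  mu <- sweep(q, 2, lib / colSums(q), `*`)
  size <- if (dispersion > 0) 1 / dispersion else Inf
  cnt <- matrix(stats::rnbinom(n_genes * ns, mu = mu, size = size), n_genes,
                dimnames = list(gene_ids, samples$sample))
  list(counts = omics_matrix(cnt, "count"), samples = samples,
       truth = list(affected_genes = affected, direction = dir))
}
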