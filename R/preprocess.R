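#' Probe quality-control filter
#'
#' Retains probes that pass, in every sample, the four array QC criteria:
#' detection p-value below `det_p_max`, bead count at least `min_beads`, a
#' GC at the probe start, and no SNP in the probe body. Samples are never
#' reordered or dropped.
#'
#' @param beta beta-value [omics_matrix()].
#' @param qc list with elements `detection_p` (probes x samples matrix),
#'   `bead_count` (probes x samples matrix), `has_gc_start` (named logical),
#'   `near_snp` (named logical).
#' @param det_p_max detection p-value threshold (probe fails at or above it).
#' @param min_beads minimum bead count.
#' @return filtered beta matrix; attribute `n_removed` gives the count.
#' @export
filter_probes <- function(beta, qc, det_p_max = 0.01, min_beads = 3) {
  probes <- rownames(beta)
  need <- c("detection_p", "bead_count", "has_gc_start", "near_snp")
  if (!all(need %in% names(qc))) {
    stop("`qc` must contain detection_p, bead_count, has_gc_start, near_snp",
         call. = FALSE)
  }
  for (el in c("detection_p", "bead_count")) {
    missing <- setdiff(probes, rownames(qc[[el]]))
    if (length(missing)) {
      stop(sprintf("qc$%s is missing probes: %s", el,
                   paste(utils::head(missing, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  for (el in c("has_gc_start", "near_snp")) {
    missing <- setdiff(probes, names(qc[[el]]))
    if (length(missing)) {
      stop(sprintf("qc$%s is missing probes: %s", el,
                   paste(utils::head(missing, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  detp <- qc$detection_p[probes, colnames(beta), drop = FALSE]
  beads <- qc$bead_count[probes, colnames(beta), drop = FALSE]
  keep <- apply(detp < det_p_max, 1, all) &
    apply(beads >= min_beads, 1, all) &
    qc$has_gc_start[probes] & !qc$near_snp[probes]
  out <- beta[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Beta / M-value transformation
#'
#' M = log2(beta / (1 - beta)) with beta clipped to `[eps, 1 - eps]`;
#' the inverse is beta = 2^M / (1 + 2^M). Strictly monotone; round trips
#' within 1e-9 away from the clipping boundary.
#'
#' @param x an [omics_matrix()] of kind `beta` (for `to = "m"`) or `m`
#'   (for `to = "beta"`).
#' @param to target scale.
#' @param eps clipping margin on the beta scale.
#' @export
beta_m_transform <- function(x, to = c("m", "beta"), eps = 1e-6) {
  to <- match.arg(to)
  from <- om_kind(x)
  if (to == "m" && from != "beta") {
    stop("input must be kind 'beta' to transform to M-values", call. = FALSE)
  }
  if (to == "beta" && from != "m") {
    stop("input must be kind 'm' to transform to beta values", call. = FALSE)
  }
  v <- om_values(x)
  out <- if (to == "m") {
    b <- pmin(pmax(v, eps), 1 - eps)
    log2(b / (1 - b))
  } else {
    2^v / (1 + 2^v)
  }
  dimnames(out) <- dimnames(v)
  omics_matrix(out, to)
}

#' Filter genes with low counts-per-million
#'
#' Removes genes whose raw CPM (count / library size x 1e6, library size =
#' column sum before filtering) is below `cpm_min` in at least `frac` of the
#' samples; equivalently keeps genes with CPM >= `cpm_min` in more than
#' `1 - frac` of samples.
#'
#' @param counts count [omics_matrix()].
#' @param cpm_min CPM threshold.
#' @param frac fraction of samples allowed below the threshold.
#' @export
filter_low_count_genes <- function(counts, cpm_min = 10, frac = 0.7) {
  stopifnot(om_kind(counts) == "count", ncol(counts) >= 1)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop(sprintf("sample(s) with zero library size: %s",
                 paste(colnames(counts)[lib == 0], collapse = ", ")),
         call. = FALSE)
  }
  cpm <- sweep(om_values(counts), 2, lib, `/`) * 1e6
  n_low <- rowSums(cpm < cpm_min)
  keep <- n_low < frac * ncol(counts) - 1e-9
  out <- counts[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' For each sample against a reference (the sample whose upper-quartile CPM
#' is closest to the mean upper quartile), per-gene log2 CPM ratios (M) and
#' average log2 CPM (A) are computed over genes expressed in both; both are
#' doubly trimmed (`logratio_trim` per tail on M, `sum_trim` per tail on A)
#' and the factor is 2 to the precision-weighted mean of the surviving M
#' values, the weights being inverse asymptotic binomial variances. Factors
#' are rescaled to a unit geometric mean.
#'
#' @param counts count [omics_matrix()].
#' @param logratio_trim fraction trimmed from each tail of M.
#' @param sum_trim fraction trimmed from each tail of A.
#' @param a_cutoff minimum A; genes below are dropped before trimming.
#' @return data.frame of class `norm_factors` with columns `sample`,
#'   `lib_size`, `factor`.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05,
                        a_cutoff = -1e10) {
  stopifnot(om_kind(counts) == "count")
  v <- om_values(counts)
  lib <- colSums(v)
  stopifnot(all(lib > 0))
  ns <- ncol(v)
  if (ns < 2) {
    warning("fewer than 2 samples: all TMM factors set to 1")
    return(structure(data.frame(sample = colnames(v), lib_size = lib,
                                factor = rep(1, ns)),
                     class = c("norm_factors", "data.frame")))
  }
  uq <- apply(v, 2, function(x) stats::quantile(x / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ns), function(j) {
    tmm_pair(v[, j], v[, ref], lib[j], lib[ref],
             logratio_trim, sum_trim, a_cutoff)
  }, numeric(1))
  f <- f / exp(mean(log(f)))                  # geometric mean 1
  structure(data.frame(sample = colnames(v), lib_size = lib, factor = f,
                       row.names = NULL),
            class = c("norm_factors", "data.frame"))
}

# one sample vs reference; follows the published TMM estimator
tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim,
                     a_cutoff) {
  p_obs <- obs / n_obs
  p_ref <- ref / n_ref
  keep <- obs > 0 & ref > 0
  m <- log2(p_obs[keep] / p_ref[keep])
  a <- (log2(p_obs[keep]) + log2(p_ref[keep])) / 2
  w <- (n_obs - obs[keep]) / (n_obs * obs[keep]) +
    (n_ref - ref[keep]) / (n_ref * ref[keep])
  fin <- is.finite(m) & is.finite(a) & a > a_cutoff
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (length(m) == 0 || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  sel <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(sel)) return(1)
  f <- 2^(sum(m[sel] / w[sel]) / sum(1 / w[sel]))
  if (!is.finite(f)) 1 else f
}

#' Normalized log2 counts per million
#'
#' `log2((count + prior) / (lib_size x factor + 2 x prior) x 1e6)`.
#'
#' @param counts count [omics_matrix()].
#' @param factors [tmm_factors()] output covering all samples (or NULL for
#'   unit factors).
#' @param prior prior count added to the numerator (twice to the
#'   denominator).
#' @export
log_cpm <- function(counts, factors = NULL, prior = 0.5) {
  stopifnot(om_kind(counts) == "count")
  v <- om_values(counts)
  lib <- colSums(v)
  f <- rep(1, ncol(v))
  if (!is.null(factors)) {
    idx <- match(colnames(v), factors$sample)
    if (anyNA(idx)) stop("`factors` does not cover all samples", call. = FALSE)
    f <- factors$factor[idx]
    lib <- factors$lib_size[idx]
  }
  eff <- lib * f
  out <- log2(sweep(v + prior, 2, eff + 2 * prior, `/`) * 1e6)
  dimnames(out) <- dimnames(v)
  omics_matrix(out, "logcpm")
}
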