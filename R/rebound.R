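#' Call differentially methylated probes
#'
#' A CpG is a DMP for a contrast when its p-value is at most `p_max` AND its
#' mean beta difference exceeds `db_min` in absolute value. Direction is the
#' sign of the beta difference (positive = hypermethylated). Significant
#' probes whose beta-difference sign contradicts the M-scale coefficient
#' sign (possible near the beta boundaries) are excluded and counted.
#'
#' @param result a `differential_result` from [test_contrast()].
#' @param delta_beta per-CpG beta differences from [mean_beta_difference()]
#'   (may also be present as a `delta_beta` column of `result`).
#' @param p_max nominal p-value threshold (inclusive).
#' @param db_min absolute beta-difference threshold (exclusive).
#' @return data.frame of feature calls: feature, p, delta_beta, estimate,
#'   direction ("hyper"/"hypo"/NA), significant; attribute `n_conflicting`.
#' @export
call_dmps <- function(result, delta_beta = NULL, p_max = 0.05,
                      db_min = 0.05) {
  if (is.null(delta_beta)) {
    if (!"delta_beta" %in% names(result)) {
      stop("no beta differences: supply `delta_beta`", call. = FALSE)
    }
    db <- result$delta_beta
  } else {
    db <- delta_beta[result$feature]
    if (anyNA(db)) stop("`delta_beta` does not cover all features",
                        call. = FALSE)
  }
  sig <- result$p <= p_max & abs(db) > db_min
  conflict <- sig & sign(db) != sign(result$estimate) & result$estimate != 0
  sig[conflict] <- FALSE
  out <- data.frame(
    feature = result$feature, p = result$p, delta_beta = unname(db),
    estimate = result$estimate,
    direction = ifelse(sig, ifelse(db > 0, "hyper", "hypo"), NA_character_),
    significant = sig, stringsAsFactors = FALSE)
  attr(out, "n_conflicting") <- sum(conflict)
  out
}

#' Call differentially expressed genes
#'
#' A gene is a DEG when its p-value is at most `p_max`; direction is the
#' contrast coefficient sign (positive = upregulated).
#'
#' @inheritParams call_dmps
#' @export
call_degs <- function(result, p_max = 0.05) {
  sig <- result$p <= p_max & result$estimate != 0
  data.frame(
    feature = result$feature, p = result$p, estimate = result$estimate,
    direction = ifelse(sig, ifelse(result$estimate > 0, "up", "down"),
                       NA_character_),
    significant = sig, stringsAsFactors = FALSE)
}

#' Identify rebound features across the two contrast windows
#'
#' A feature rebounds when it is significant in both the during-pregnancy
#' window (3rd-1st trimester) and the post-partum window (PP-3rd) with
#' opposite directions. Features significant in both windows with the SAME
#' direction are returned separately as non-rebound overlap.
#'
#' @param calls_w1,calls_w2 [call_dmps()]/[call_degs()] outputs for the two
#'   windows over the same feature universe.
#' @return list: `rebound` (data.frame feature, pattern, p_w1, p_w2),
#'   `same_direction` (data.frame feature, direction), `n_significant_both`.
#' @export
find_rebound <- function(calls_w1, calls_w2) {
  if (!identical(sort(calls_w1$feature), sort(calls_w2$feature))) {
    stop("the two windows cover different feature universes", call. = FALSE)
  }
  w2 <- calls_w2[match(calls_w1$feature, calls_w2$feature), ]
  both <- calls_w1$significant & w2$significant
  opp <- both & calls_w1$direction != w2$direction
  same <- both & calls_w1$direction == w2$direction
  rebound <- data.frame(
    feature = calls_w1$feature[opp],
    pattern = paste(calls_w1$direction[opp], w2$direction[opp], sep = "-"),
    p_w1 = calls_w1$p[opp], p_w2 = w2$p[opp], stringsAsFactors = FALSE)
  list(rebound = rebound,
       same_direction = data.frame(feature = calls_w1$feature[same],
                                   direction = calls_w1$direction[same],
                                   stringsAsFactors = FALSE),
       n_significant_both = sum(both))
}

#' Shared rebound features across disease and control groups
#'
#' Features rebounding in both groups with the identical direction pattern;
#' also emits, per window, the 2x2 direction-agreement percentages over
#' features rebounding in both groups.
#'
#' @param rebound_ms,rebound_hc [find_rebound()] results for the two groups.
#' @return list: `shared` (data.frame feature, pattern), `quadrants` (list
#'   of two 2x2 percentage tables, one per window), `n_rebound_both`.
#' @export
shared_rebound <- function(rebound_ms, rebound_hc) {
  ms <- rebound_ms$rebound
  hc <- rebound_hc$rebound
  common <- intersect(ms$feature, hc$feature)
  msc <- ms[match(common, ms$feature), ]
  hcc <- hc[match(common, hc$feature), ]
  agree <- msc$pattern == hcc$pattern
  shared <- data.frame(feature = common[agree],
                       pattern = msc$pattern[agree],
                       stringsAsFactors = FALSE)
  quadrants <- list()
  if (length(common)) {
    d_ms <- do.call(rbind, strsplit(msc$pattern, "-", fixed = TRUE))
    d_hc <- do.call(rbind, strsplit(hcc$pattern, "-", fixed = TRUE))
    for (w in 1:2) {
      tab <- table(MS = d_ms[, w], HC = d_hc[, w])
      quadrants[[paste0("window", w)]] <- 100 * tab / sum(tab)
    }
  }
  list(shared = shared, quadrants = quadrants,
       n_rebound_both = length(common))
}

#' Map CpGs to genes (differentially methylated genes)
#'
#' The union of all genes annotated to any input CpG; a CpG may map to
#' several genes, and unannotated CpGs are dropped with a count.
#'
#' @param cpgs CpG identifiers.
#' @param annotation data.frame with columns `cpg`, `gene`.
#' @return sorted character vector of genes; attribute `n_unannotated`.
#' @export
map_cpgs_to_genes <- function(cpgs, annotation) {
  hit <- annotation[annotation$cpg %in% cpgs, , drop = FALSE]
  genes <- sort(unique(hit$gene))
  structure(genes,
            n_unannotated = length(setdiff(cpgs, annotation$cpg)))
}

#' Pearson correlation between two contrasts' effect estimates
#'
#' @param result_a,result_b `differential_result`s sharing (part of) a
#'   feature universe.
#' @return list: `r`, `p`, `n` (shared features).
#' @export
contrast_correlation <- function(result_a, result_b) {
  common <- intersect(result_a$feature, result_b$feature)
  if (length(common) < 3) {
    stop("fewer than 3 shared features", call. = FALSE)
  }
  a <- result_a$estimate[match(common, result_a$feature)]
  b <- result_b$estimate[match(common, result_b$feature)]
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common))
}

#' Fraction of rebound features not returning to the pre-pregnancy baseline
#'
#' For each rebound feature, compares the post-partum level against the
#' before-pregnancy (BP) baseline: a feature is "incompletely reversed" when
#' its PP-BP contrast still deviates in the same direction as its T3-BP
#' excursion.
#'
#' @param result_pp_bp,result_t3_bp `differential_result`s for the PP-BP and
#'   3rd-trimester-BP contrasts.
#' @param features rebound feature ids to evaluate.
#' @return fraction in [0,1].
#' @export
incomplete_rebound_fraction <- function(result_pp_bp, result_t3_bp,
                                        features) {
  a <- result_pp_bp[match(features, result_pp_bp$feature), ]
  b <- result_t3_bp[match(features, result_t3_bp$feature), ]
  mean(sign(a$estimate) == sign(b$estimate) & a$estimate != 0)
}
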