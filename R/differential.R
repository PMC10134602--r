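#' Build the group-time design matrix
#'
#' One intercept, one indicator per observed (group, timepoint) combination
#' except each group's reference timepoint, and one column per numeric
#' covariate. Grouping disease and time under a single term captures
#' group-specific time effects; a group missing a timepoint (e.g. no
#' pre-pregnancy samples in controls) simply contributes no column for that
#' cell.
#'
#' @param samples sample table with columns `sample`, `donor`, `group`,
#'   `timepoint` and every covariate.
#' @param covariates character vector of numeric covariate columns.
#' @param reference_time the baseline timepoint dropped for every group.
#' @return list of class `design_matrix`: `X` (samples x columns),
#'   `blocks` (donor factor), `samples`, `reference_time`.
#' @export
build_design <- function(samples,
                         covariates = c("age", "memory", "viability"),
                         reference_time = "T1") {
  stopifnot(all(c("sample", "donor", "group", "timepoint") %in%
                  names(samples)))
  if (!reference_time %in% samples$timepoint) {
    stop(sprintf("reference time '%s' not present in the data",
                 reference_time), call. = FALSE)
  }
  for (cv in covariates) {
    if (!cv %in% names(samples)) {
      stop(sprintf("covariate '%s' missing from sample table", cv),
           call. = FALSE)
    }
    if (!is.numeric(samples[[cv]])) {
      stop(sprintf("covariate '%s' is not numeric", cv), call. = FALSE)
    }
  }
  n <- nrow(samples)
  cells <- unique(samples[, c("group", "timepoint")])
  cells <- cells[cells$timepoint != reference_time, , drop = FALSE]
  cells <- cells[order(cells$group, cells$timepoint), , drop = FALSE]
  X <- matrix(0, n, 1 + nrow(cells) + length(covariates))
  X[, 1] <- 1
  cn <- "(Intercept)"
  for (i in seq_len(nrow(cells))) {
    X[, 1 + i] <- as.numeric(samples$group == cells$group[i] &
                               samples$timepoint == cells$timepoint[i])
    cn <- c(cn, paste(cells$group[i], cells$timepoint[i], sep = "_"))
  }
  for (j in seq_along(covariates)) {
    X[, 1 + nrow(cells) + j] <- samples[[covariates[j]]]
    cn <- c(cn, covariates[j])
  }
  colnames(X) <- cn
  rownames(X) <- samples$sample
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("design is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(X = X, blocks = factor(samples$donor), samples = samples,
                 reference_time = reference_time),
            class = "design_matrix")
}

#' Contrast vector between two (group, timepoint) cells
#'
#' Returns the coefficient contrast estimating `time_b - time_a` within
#' `group`; the reference timepoint maps to a zero column.
#'
#' @param design a [build_design()] result.
#' @param group group label.
#' @param time_b,time_a timepoints; the contrast is `time_b - time_a`.
#' @export
time_contrast <- function(design, group, time_b, time_a) {
  cn <- colnames(design$X)
  cvec <- stats::setNames(numeric(length(cn)), cn)
  for (s in list(c(time_b, 1), c(time_a, -1))) {
    tp <- s[1]
    if (tp == design$reference_time) next
    col <- paste(group, tp, sep = "_")
    if (!col %in% cn) {
      stop(sprintf("no design column for group %s at %s", group, tp),
           call. = FALSE)
    }
    cvec[col] <- cvec[col] + as.numeric(s[2])
  }
  cvec
}

#' Consensus intra-donor correlation of model residuals
#'
#' Estimates a single intra-donor (block) correlation shared by all
#' features, in the spirit of a consensus `duplicateCorrelation`. Per
#' feature, OLS residuals give two quadratic forms: the within-donor
#' off-diagonal sum and the residual sum of squares. Their expectations
#' under an equicorrelated donor model are linear in rho with coefficients
#' that are traces of known projection products, so the per-feature ratio
#' yields a method-of-moments estimate corrected for the hat-matrix
#' projection. The per-feature estimates are Fisher-z transformed, averaged
#' over features with 5% tail trimming, and transformed back.
#'
#' @param data an [omics_matrix()] (features x samples), typically M-values
#'   or logCPM.
#' @param design a [build_design()] result.
#' @param trim trimming fraction for the consensus mean.
#' @return consensus correlation (scalar); attribute `per_feature` holds the
#'   clamped per-feature estimates.
#' @export
estimate_block_correlation <- function(data, design, trim = 0.05) {
  X <- design$X
  blocks <- design$blocks
  n <- nrow(X); p <- ncol(X)
  if (ncol(data) != n) stop("data/design sample mismatch", call. = FALSE)
  tab <- table(blocks)
  if (sum(tab >= 2) < 2) {
    warning("fewer than 2 donors with repeated samples: rho set to 0")
    return(structure(0, per_feature = numeric(0)))
  }
  B <- outer(as.character(blocks), as.character(blocks), `==`) * 1
  P <- B - diag(n)                              # within-block off-diagonal
  H <- X %*% chol2inv(chol(crossprod(X))) %*% t(X)
  M <- diag(n) - H
  MBM <- M %*% B %*% M
  c1 <- sum(P * M)                              # tr(P M)
  c2 <- sum(P * MBM)                            # tr(P M B M)
  d1 <- n - p                                   # tr(M)
  d2 <- sum(diag(MBM))                          # tr(M B M)
  R <- M %*% t(om_values(data))                 # residuals, samples x features
  S2 <- colSums(R^2)
  bs <- rowsum(R, blocks)                       # block sums per feature
  bs2 <- rowsum(R^2, blocks)
  S1 <- colSums(bs^2 - bs2)                     # sum over within-block pairs*2
  ok <- S2 > 0
  t_g <- S1[ok] / S2[ok]
  rho_g <- (t_g * d1 - c1) / ((c2 - c1) - t_g * (d2 - d1))
  lo <- -1 / (max(tab) - 1) + 1e-6
  rho_g <- pmin(pmax(rho_g, lo), 0.999)
  z <- atanh(rho_g)
  rho <- tanh(mean(z, trim = trim))
  structure(rho, per_feature = rho_g)
}

#' Precision weights from the mean-variance trend
#'
#' Fits OLS per gene on logCPM, smooths the square-root residual standard
#' deviation against average log2 count with `lowess`, and assigns each
#' observation the weight `predicted^-4` at its fitted log2 count.
#'
#' @param counts count [omics_matrix()].
#' @param design a [build_design()] result.
#' @param factors [tmm_factors()] output (or NULL).
#' @param span lowess span.
#' @return genes x samples weight matrix (all positive).
#' @export
voom_weights <- function(counts, design, factors = NULL, span = 0.5) {
  stopifnot(om_kind(counts) == "count")
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  if (n - p < 1) stop("no residual degrees of freedom", call. = FALSE)
  lcpm <- log_cpm(counts, factors)
  lib <- colSums(om_values(counts))
  f <- rep(1, n)
  if (!is.null(factors)) {
    idx <- match(colnames(counts), factors$sample)
    f <- factors$factor[idx]
    lib <- factors$lib_size[idx]
  }
  eff <- lib * f
  if (nrow(counts) < 50) {
    warning("fewer than 50 genes: uniform precision weights")
    return(matrix(1, nrow(counts), n, dimnames = dimnames(counts)))
  }
  fit <- stats::lm.fit(X, t(om_values(lcpm)))
  fitted <- t(om_values(lcpm)) - fit$residuals  # samples x genes
  s <- sqrt(colSums(fit$residuals^2) / (n - p))
  # mean log2 count per gene (shift logCPM back to the count scale)
  sx <- rowMeans(om_values(lcpm)) + mean(log2(eff + 1)) - log2(1e6)
  sy <- sqrt(s)
  lo <- stats::lowess(sx, sy, f = span)
  pred <- stats::approxfun(lo$x, lo$y, rule = 2)
  # per-observation fitted log2 count
  lambda <- t(fitted) + matrix(log2(eff + 1), nrow(counts), n, byrow = TRUE) -
    log2(1e6)
  w <- pred(lambda)^(-4)
  w[!is.finite(w)] <- max(w[is.finite(w)])
  w <- pmax(w, 1e-8)
  dim(w) <- dim(lambda)
  dimnames(w) <- dimnames(counts)
  w
}

#' Per-feature generalized least squares with equicorrelated donor blocks
#'
#' Fits every feature by GLS with covariance proportional to
#' `D R D`, where `R` has unit diagonal and correlation `rho` between
#' samples of the same donor and `D = diag(1/sqrt(w))` carries optional
#' per-observation precision weights.
#'
#' @param data features x samples [omics_matrix()] (M-values or logCPM; a
#'   count matrix is not accepted).
#' @param design a [build_design()] result.
#' @param rho intra-donor correlation.
#' @param weights optional features x samples weight matrix.
#' @return list of class `feature_fits`: `coefficients` (features x p),
#'   `cov_unscaled` (p x p matrix, or features-list when weighted), `s2`,
#'   `df_residual`, `rho`, column names.
#' @export
fit_feature_models <- function(data, design, rho = 0, weights = NULL) {
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  stopifnot(ncol(data) == n)
  if (!is.null(weights)) {
    stopifnot(all(dim(weights) == dim(data)), all(weights > 0))
  }
  blocks <- design$blocks
  Rcor <- diag(n)
  same <- outer(as.character(blocks), as.character(blocks), `==`)
  Rcor[same] <- rho
  diag(Rcor) <- 1
  U <- tryCatch(chol(Rcor), error = function(e) {
    stop("block correlation matrix is not positive definite (rho too negative)",
         call. = FALSE)
  })
  tU <- t(U)
  V <- om_values(data)
  G <- nrow(V)
  if (is.null(weights)) {
    Xs <- forwardsolve(tU, X)
    Ys <- forwardsolve(tU, t(V))
    fit <- stats::lm.fit(Xs, Ys)
    coefs <- t(as.matrix(fit$coefficients))
    res <- as.matrix(fit$residuals)
    s2 <- colSums(res^2) / (n - p)
    covu <- chol2inv(chol(crossprod(Xs)))
    dimnames(covu) <- list(colnames(X), colnames(X))
  } else {
    coefs <- matrix(NA_real_, G, p)
    s2 <- numeric(G)
    covu <- vector("list", G)
    for (g in seq_len(G)) {
      sw <- sqrt(weights[g, ])
      Xg <- forwardsolve(tU, X * sw)
      yg <- forwardsolve(tU, V[g, ] * sw)
      qr_g <- qr(Xg)
      coefs[g, ] <- qr.coef(qr_g, yg)
      rs <- qr.resid(qr_g, yg)
      s2[g] <- sum(rs^2) / (n - p)
      Rg <- qr.R(qr_g)[, order(qr_g$pivot), drop = FALSE]
      covu[[g]] <- chol2inv(chol(crossprod(Rg)))
    }
  }
  rownames(coefs) <- rownames(V)
  colnames(coefs) <- colnames(X)
  structure(list(coefficients = coefs, cov_unscaled = covu, s2 = s2,
                 df_residual = rep(n - p, G), rho = rho,
                 coef_names = colnames(X), weighted = !is.null(weights)),
            class = "feature_fits")
}

# Newton inversion of the trigamma function (for prior-df estimation).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderation of residual variances
#'
#' Matches the first two moments of `log(s_g^2)` to a scaled F distribution
#' (trigamma inversion) to estimate a prior degree of freedom `d0` and prior
#' variance `s0^2`, then shrinks every feature's variance to
#' `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)`. `d0` may be infinite, in which
#' case all posterior variances equal `s0^2`; `d0 = 0` disables shrinkage.
#'
#' @param fits a [fit_feature_models()] result.
#' @param d0 optional fixed prior df (overrides estimation).
#' @return list of class `moderation`: `d0`, `s0_2`, `s2_post`, `df_total`.
#' @export
ebayes_moderate <- function(fits, d0 = NULL) {
  s2 <- fits$s2
  dg <- fits$df_residual
  if (length(s2) < 2 && is.null(d0)) {
    stop("need >= 2 features to estimate the variance prior", call. = FALSE)
  }
  ok <- s2 > 0
  if (is.null(d0)) {
    z <- log(s2[ok])
    e <- z - digamma(dg[ok] / 2) + log(dg[ok] / 2)
    emean <- mean(e)
    nn <- length(e)
    evar <- sum((e - emean)^2) / (nn - 1) - mean(trigamma(dg[ok] / 2))
    if (evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_2 <- exp(emean)
    }
  } else {
    s0_2 <- if (d0 > 0) exp(mean(log(s2[ok]))) else NA_real_
  }
  s2_post <- if (is.infinite(d0)) {
    rep(s0_2, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s0_2 + dg * s2) / (d0 + dg)
  }
  structure(list(d0 = d0, s0_2 = s0_2, s2_post = s2_post,
                 df_total = dg + d0),
            class = "moderation")
}

#' Moderated contrast test
#'
#' Tests `c' beta` per feature with the moderated variance: the statistic is
#' `c' beta_hat / (sqrt(c' C c) s_post)` on `d0 + d_g` degrees of freedom,
#' with Benjamini-Hochberg adjustment across features.
#'
#' @param fits a [fit_feature_models()] result.
#' @param moderation an [ebayes_moderate()] result for the same fits.
#' @param contrast numeric contrast vector over the design coefficients
#'   (named vectors are matched by name).
#' @param name optional contrast label stored as an attribute.
#' @return `differential_result` data.frame: feature, estimate, se, t, p,
#'   adj_p.
#' @export
test_contrast <- function(fits, moderation, contrast, name = NULL) {
  cn <- fits$coef_names
  if (!is.null(names(contrast))) {
    cvec <- stats::setNames(numeric(length(cn)), cn)
    extra <- setdiff(names(contrast), cn)
    if (length(extra)) {
      stop(sprintf("contrast references unknown coefficient(s): %s",
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
    cvec[names(contrast)] <- contrast
  } else {
    if (length(contrast) != length(cn)) {
      stop("contrast length must equal the number of coefficients",
           call. = FALSE)
    }
    cvec <- contrast
  }
  est <- drop(fits$coefficients %*% cvec)
  vu <- if (fits$weighted) {
    vapply(fits$cov_unscaled, function(C) drop(cvec %*% C %*% cvec),
           numeric(1))
  } else {
    rep(drop(cvec %*% fits$cov_unscaled %*% cvec), length(est))
  }
  se <- sqrt(vu * moderation$s2_post)
  tstat <- ifelse(se > 0, est / se, 0)
  p <- 2 * stats::pt(-abs(tstat), df = moderation$df_total)
  p[se == 0 & est == 0] <- 1
  out <- data.frame(feature = rownames(fits$coefficients), estimate = est,
                    se = se, t = tstat, p = p,
                    adj_p = stats::p.adjust(p, "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "contrast") <- cvec
  attr(out, "name") <- name
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Mean beta difference between two timepoints within a group
#'
#' `mean(beta at time_b) - mean(beta at time_a)` over the group's samples,
#' on the beta scale.
#'
#' @param beta beta-value [omics_matrix()].
#' @param samples sample table.
#' @param group group label.
#' @param time_a,time_b timepoints; the difference is `time_b - time_a`.
#' @return named numeric vector of per-CpG differences.
#' @export
mean_beta_difference <- function(beta, samples, group, time_a, time_b) {
  stopifnot(om_kind(beta) == "beta")
  sel_a <- samples$sample[samples$group == group & samples$timepoint == time_a]
  sel_b <- samples$sample[samples$group == group & samples$timepoint == time_b]
  if (length(sel_a) == 0 || length(sel_b) == 0) {
    stop(sprintf("no samples for group %s at %s", group,
                 if (length(sel_a) == 0) time_a else time_b), call. = FALSE)
  }
  rowMeans(om_values(beta)[, sel_b, drop = FALSE]) -
    rowMeans(om_values(beta)[, sel_a, drop = FALSE])
}

#' Differential test for the in vitro activation state
#'
#' Fits expression with a resting/activated indicator plus the per-sample
#' activation level as covariate (so the continuous level does not confound
#' the state effect), using precision weights and moderated statistics;
#' genes with BH-adjusted p <= `fdr_max` are flagged activation-associated.
#'
#' @param counts count [omics_matrix()].
#' @param samples sample table with columns `state`
#'   (resting/activated) and `activation_level`, plus any extra covariates.
#' @param covariates additional numeric covariates.
#' @param fdr_max adjusted-p threshold for flagging.
#' @return `differential_result` with an extra logical column `activation`.
#' @export
activation_contrast <- function(counts, samples, covariates = character(),
                                fdr_max = 0.05) {
  if (length(unique(samples$state)) < 2) {
    stop("need both resting and activated samples", call. = FALSE)
  }
  s2 <- samples
  s2$group <- "all"
  s2$timepoint <- ifelse(s2$state == "activated", "T2", "T1")
  design <- build_design(s2, covariates = c("activation_level", covariates),
                         reference_time = "T1")
  keep <- filter_low_count_genes(counts)
  nf <- tmm_factors(keep)
  w <- voom_weights(keep, design, nf)
  lcpm <- log_cpm(keep, nf)
  rho <- 0
  if (any(table(samples$donor) >= 2)) {
    rho <- as.numeric(estimate_block_correlation(lcpm, design))
  }
  fits <- fit_feature_models(lcpm, design, rho = rho, weights = w)
  mod <- ebayes_moderate(fits)
  res <- test_contrast(fits, mod, c(all_T2 = 1), name = "activated-resting")
  res$activation <- res$adj_p <= fdr_max
  res
}
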