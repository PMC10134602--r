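sim_samples <- function(n_donors = 4L, groups = c("MS", "HC"),
                        timepoints = c("T1", "T2", "T3", "PP"), seed = 1) {
  set.seed(seed)
  rows <- expand.grid(timepoint = timepoints,
                      donor_i = seq_len(n_donors), group = groups,
                      stringsAsFactors = FALSE)
  rows$donor <- sprintf("%s%02d", rows$group, rows$donor_i)
  rows$sample <- sprintf("%s_%s", rows$donor, rows$timepoint)
  rows$age <- rep(round(rnorm(n_donors * length(groups), 33, 4), 1),
                  each = length(timepoints))
  rows$memory <- round(runif(nrow(rows), 0.3, 0.7), 3)
  rows$viability <- round(runif(nrow(rows), 0.7, 0.99), 3)
  rows[, c("sample", "donor", "group", "timepoint", "age", "memory",
           "viability")]
}

test_that("the design holds one indicator per non-reference group-time cell
           plus the covariates", {
  s <- sim_samples()
  d <- build_design(s)
  expect_equal(ncol(d$X), 1 + 2 * 3 + 3)
  expect_true(all(c("MS_T3", "HC_PP", "age", "memory", "viability") %in%
                    colnames(d$X)))
  # single group, single timepoint: intercept + covariates only
  s1 <- s[s$group == "MS" & s$timepoint == "T1", ]
  d1 <- build_design(s1, reference_time = "T1")
  expect_identical(colnames(d1$X),
                   c("(Intercept)", "age", "memory", "viability"))
  # a group missing a timepoint simply contributes no column
  s2 <- s[!(s$group == "HC" & s$timepoint == "PP"), ]
  d2 <- build_design(s2)
  expect_false("HC_PP" %in% colnames(d2$X))
  # collinear covariates are named in the error
  s3 <- s
  s3$age2 <- s3$age
  expect_error(build_design(s3, covariates = c("age", "age2")),
               "age2")
  expect_error(build_design(s, reference_time = "BP"), "BP")
})

test_that("contrast vectors map timepoint differences onto coefficients", {
  d <- build_design(sim_samples())
  cv <- time_contrast(d, "MS", "T3", "T1")   # T1 = reference -> single +1
  expect_equal(unname(cv["MS_T3"]), 1)
  expect_equal(sum(cv != 0), 1)
  cv2 <- time_contrast(d, "MS", "PP", "T3")
  expect_equal(unname(cv2[c("MS_PP", "MS_T3")]), c(1, -1))
  expect_error(time_contrast(d, "MS", "BP", "T1"), "BP")
})

test_that("GLS with rho = 0 reduces to OLS and matches a direct GLS solve
           otherwise", {
  s <- sim_samples(n_donors = 5L, seed = 2)
  d <- build_design(s)
  set.seed(7)
  V <- matrix(rnorm(20 * nrow(s)), 20,
              dimnames = list(paste0("f", 1:20), s$sample))
  x <- omics_matrix(V, "m")
  fits0 <- fit_feature_models(x, d, rho = 0)
  ref <- lm.fit(d$X, t(V))
  expect_equal(fits0$coefficients, t(ref$coefficients), tolerance = 1e-10)
  # exact linear data: zero residual variance, exact coefficients
  bexact <- seq_len(ncol(d$X))
  yx <- matrix(drop(d$X %*% bexact), 1, dimnames = list("f", s$sample))
  fx <- fit_feature_models(omics_matrix(yx, "m"), d)
  expect_equal(unname(fx$coefficients[1, ]), bexact, tolerance = 1e-8)
  expect_lt(fx$s2[1], 1e-16)
  # rho = 0.5 against the normal-equation oracle
  rho <- 0.5
  same <- outer(s$donor, s$donor, `==`)
  Sigma <- ifelse(same, rho, 0); diag(Sigma) <- 1
  fits <- fit_feature_models(x, d, rho = rho)
  orc <- oracle_gls(V[3, ], d$X, Sigma)
  expect_equal(unname(fits$coefficients[3, ]), unname(orc$coef),
               tolerance = 1e-8)
  expect_equal(unname(fits$cov_unscaled), unname(orc$cov_unscaled),
               tolerance = 1e-8)
  # weighted fits agree with a weight-scaled oracle
  set.seed(8)
  W <- matrix(runif(length(V), 0.5, 2), nrow(V))
  fw <- fit_feature_models(x, d, rho = rho, weights = W)
  Dg <- diag(1 / sqrt(W[3, ]))
  orc_w <- oracle_gls(V[3, ], d$X, Dg %*% Sigma %*% Dg)
  expect_equal(unname(fw$coefficients[3, ]), unname(orc_w$coef),
               tolerance = 1e-8)
  expect_equal(unname(fw$cov_unscaled[[3]]), unname(orc_w$cov_unscaled),
               tolerance = 1e-8)
  # infeasible rho errors
  expect_error(fit_feature_models(x, d, rho = -0.9), "positive definite")
})

test_that("all-singleton donor blocks yield rho 0 with a warning", {
  s <- sim_samples(timepoints = "T2", seed = 3)
  d <- build_design(s, reference_time = "T2")
  x <- omics_matrix(matrix(rnorm(10 * nrow(s)), 10,
                           dimnames = list(paste0("f", 1:10), s$sample)),
                    "m")
  expect_warning(rho <- estimate_block_correlation(x, d), "repeated")
  expect_equal(as.numeric(rho), 0)
})

test_that("variance moderation limits: no shrinkage reproduces the ordinary
           t-test, infinite prior df gives a z-like statistic", {
  cfg <- small_cohort(n_donors = 4L, n_cpgs = 120L, n_genes = 20L,
                      frac_rebound = 0, rho_donor = 0)
  coh <- generate_cohort(cfg)
  m <- beta_m_transform(coh$beta, "m")
  d <- build_design(coh$samples)
  fits <- fit_feature_models(m, d, rho = 0)
  mod0 <- ebayes_moderate(fits, d0 = 0)
  res0 <- test_contrast(fits, mod0, time_contrast(d, "MS", "T3", "T1"))
  # full-stack textbook check: per-feature OLS t statistic
  cv <- setNames(numeric(ncol(d$X)), colnames(d$X)); cv["MS_T3"] <- 1
  XtXinv <- solve(crossprod(d$X))
  vu <- drop(cv %*% XtXinv %*% cv)
  for (i in c(1, 50, 120)) {
    f <- lm.fit(d$X, om_values(m)[i, ])
    s2 <- sum(f$residuals^2) / f$df.residual
    t_ref <- f$coefficients["MS_T3"] / sqrt(vu * s2)
    expect_equal(res0$t[i], unname(t_ref), tolerance = 1e-8)
    p_ref <- 2 * pt(-abs(t_ref), f$df.residual)
    expect_equal(res0$p[i], unname(p_ref), tolerance = 1e-8)
  }
  # d0 = Inf: statistic uses the pooled variance everywhere
  modInf <- ebayes_moderate(fits, d0 = Inf)
  expect_true(all(modInf$s2_post == modInf$s2_post[1]))
  resInf <- test_contrast(fits, modInf, cv)
  expect_equal(resInf$t, res0$estimate / sqrt(vu * modInf$s2_post),
               tolerance = 1e-12)
  # posterior variance is always between the prior and the sample variance
  mod <- ebayes_moderate(fits)
  expect_true(all(mod$s2_post >= pmin(mod$s0_2, fits$s2) - 1e-12))
  expect_true(all(mod$s2_post <= pmax(mod$s0_2, fits$s2) + 1e-12))
})

test_that("moment matching recovers the prior variance from scaled
           chi-square draws", {
  set.seed(11)
  dg <- 50L
  fits <- structure(list(s2 = 4 * rchisq(5000, dg) / dg,
                         df_residual = rep(dg, 5000)),
                    class = "feature_fits")
  mod <- ebayes_moderate(fits)
  expect_gt(mod$s0_2, 3.6)
  expect_lt(mod$s0_2, 4.4)
  # a genuinely spread variance prior yields a finite d0 of the right order
  set.seed(12)
  d0_true <- 8
  s2g <- 4 * d0_true / rchisq(5000, d0_true)        # scaled inverse chi-sq
  fits2 <- structure(list(s2 = s2g * rchisq(5000, dg) / dg,
                          df_residual = rep(dg, 5000)),
                     class = "feature_fits")
  mod2 <- ebayes_moderate(fits2)
  expect_gt(mod2$d0, 4); expect_lt(mod2$d0, 16)
  # identical variances: d0 infinite without overflow
  fits3 <- structure(list(s2 = rep(2, 100), df_residual = rep(10L, 100)),
                     class = "feature_fits")
  mod3 <- ebayes_moderate(fits3)
  expect_true(is.infinite(mod3$d0))
  expect_true(all(mod3$s2_post == mod3$s0_2))
  # the log-scale moment map assumes chi-square spread, so a degenerate
  # sample overstates s0^2 by exp(log(d/2) - digamma(d/2)) ~ 11% at d = 10
  expect_lt(abs(mod3$s0_2 - 2) / 2, 0.15)
})

test_that("contrast tests recover a planted effect and behave at the
           degenerate contrast", {
  cfg <- small_cohort(n_donors = 8L, n_cpgs = 500L, n_genes = 20L,
                      frac_rebound = 0.1, seed = 21)
  coh <- generate_cohort(cfg)
  m <- beta_m_transform(coh$beta, "m")
  d <- build_design(coh$samples)
  rho <- as.numeric(estimate_block_correlation(m, d))
  fits <- fit_feature_models(m, d, rho = rho)
  mod <- ebayes_moderate(fits)
  res <- test_contrast(fits, mod, time_contrast(d, "MS", "T3", "T1"))
  planted <- coh$truth$rebound_cpgs
  est <- res$estimate[res$feature %in% planted] *
    coh$truth$cpg_direction[planted]
  expect_gt(mean(est), 1.8)
  expect_lt(mean(est), 2.2)
  # zero contrast: estimate 0, p 1
  res0 <- test_contrast(fits, mod, setNames(numeric(ncol(d$X)),
                                            colnames(d$X)))
  expect_true(all(res0$estimate == 0))
  expect_true(all(res0$p == 1))
  # determinism
  res2 <- test_contrast(fits, mod, time_contrast(d, "MS", "T3", "T1"))
  expect_identical(res, res2)
  # unknown coefficient errors
  expect_error(test_contrast(fits, mod, c(NOPE = 1)), "NOPE")
})

test_that("mean beta differences are group means with antisymmetry", {
  s <- sim_samples(n_donors = 2L, seed = 4)
  b <- matrix(0.40, 3, nrow(s), dimnames = list(paste0("cg", 1:3), s$sample))
  b[, s$timepoint == "T3"] <- 0.47
  beta <- omics_matrix(b, "beta")
  db <- mean_beta_difference(beta, s, "MS", "T1", "T3")
  expect_equal(unname(db), rep(0.07, 3), tolerance = 1e-12)
  db_rev <- mean_beta_difference(beta, s, "MS", "T3", "T1")
  expect_equal(db, -db_rev)
  expect_equal(unname(mean_beta_difference(beta, s, "MS", "T1", "T2")),
               rep(0, 3))
  expect_error(mean_beta_difference(beta, s, "MS", "T1", "BP"), "BP")
})

test_that("the activation contrast flags planted genes and only them", {
  act <- generate_activation_cohort(n_per_state = 20L, n_genes = 1500L,
                                    n_affected = 100L, lfc = 2, seed = 31)
  res <- activation_contrast(act$counts, act$samples)
  flagged <- res$feature[res$activation]
  expect_gte(length(intersect(flagged, act$truth$affected_genes)), 90)
  null_flagged <- setdiff(flagged, act$truth$affected_genes)
  expect_lte(length(null_flagged) / max(length(flagged), 1), 0.1)
  # no planted effect: flagged fraction bounded by the FDR level
  act0 <- generate_activation_cohort(n_per_state = 10L, n_genes = 800L,
                                     n_affected = 0L, seed = 32)
  res0 <- activation_contrast(act0$counts, act0$samples)
  expect_lte(mean(res0$activation), 0.05)
  # single state errors
  one <- act$samples[act$samples$state == "resting", ]
  expect_error(
    activation_contrast(act$counts[, one$sample], one), "resting")
})
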