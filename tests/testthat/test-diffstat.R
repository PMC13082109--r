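# Per-feature models, contrasts, degrees of freedom, diagnostics, FDR.

test_that("ROI means: arithmetic, single pixel, brute-force group-by", {
  ints <- cbind(c(1, 2, 3, 6), c(10, 10, 10, 10))
  run <- toy_run(2, 2, ints, run_id = "r1")
  masks <- list(r1 = roi_mask(c("roi", "roi", "roi", "roi"), "external"))
  e <- msi_experiment(list(run), data.frame(run_id = "r1", subject = "s1",
                                            condition = "A", tissue = "T1"))
  s <- summarize_roi_means(e, masks, "roi")
  expect_equal(s$ybar, c(3, 10))
  expect_equal(s$n_pixels, c(4, 4))
  # single-pixel ROI
  masks1 <- list(r1 = roi_mask(c("roi", rep("bg", 3)), "external"))
  s1 <- summarize_roi_means(e, masks1, "roi")
  expect_equal(s1$ybar, c(1, 10))
  # brute-force group-by over a 3-run toy
  set.seed(2)
  runs <- lapply(1:3, function(i) toy_run(3, 2,
    matrix(stats::rexp(12, 1 / 10), 6, 2), run_id = paste0("r", i)))
  e3 <- toy_experiment(runs)
  masks3 <- stats::setNames(lapply(1:3, function(i) {
    roi_mask(sample(c("roi", "bg"), 6, TRUE, prob = c(.8, .2)), "external")
  }), paste0("r", 1:3))
  s3 <- summarize_roi_means(e3, masks3, "roi")
  for (i in 1:3) for (f in 1:2) {
    sel <- masks3[[i]]$labels == "roi"
    expect_equal(s3$ybar[s3$run_id == paste0("r", i)][f],
                 mean(runs[[i]]$intensities[sel, f]))
  }
  # run without labelled pixels errors
  masks_bad <- masks3; masks_bad[["r2"]]$labels <- rep("bg", 6)
  expect_error(summarize_roi_means(e3, masks_bad, "roi"), "r2")
})

test_that("REML equals balanced-ANOVA closed forms at 1e-8 relative tolerance", {
  for (seed in c(1, 7, 19)) {
    summ <- balanced_summary(seed, I = 4, var_subject = 4, var_tech = 1,
                             n_features = 3)
    fits <- fit_roi_model(summ, model_spec("M3"))
    vc <- balanced_variance_components(summ, truncate = TRUE)
    for (i in seq_along(fits)) {
      expect_equal(fits[[i]]$sigma2, vc$sigma2[i], tolerance = 1e-8)
      expect_equal(fits[[i]]$sigma2_subj, vc$sigma2_subj[i],
                   tolerance = 1e-8)
    }
  }
})

test_that("REML matches lme4 on unbalanced data (independent oracle)", {
  skip_if_not_installed("lme4")
  summ <- balanced_summary(5, I = 5, var_subject = 3, var_tech = 2)
  summ <- summ[-c(2, 9), ]                  # break the balance
  class(summ) <- c("roi_summary", "data.frame")
  fit <- fit_roi_model(summ, model_spec("M3"), features = summ$mz[1])
  m <- lme4::lmer(ybar ~ condition * tissue + (1 | subject), data = summ,
                  REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(fit$sigma2_subj, vc$vcov[1], tolerance = 1e-5)
  expect_equal(fit$sigma2, vc$vcov[2], tolerance = 1e-5)
  expect_false(fit$balanced)
})

test_that("M1 reproduces the pooled two-sample t-test exactly", {
  for (seed in c(3, 11)) {
    summ <- balanced_summary(seed, I = 4, var_subject = 2, var_tech = 1,
                             cond_effect = 1)
    fit <- fit_roi_model(summ, model_spec("M1"), features = summ$mz[1])
    ct <- contrast_test(fit, "A")
    sub <- summ[summ$tissue == "T1", ]
    tt <- stats::t.test(ybar ~ condition, data = sub, var.equal = TRUE)
    expect_equal(ct$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(ct$p, tt$p.value, tolerance = 1e-10)
    expect_equal(ct$df, unname(tt$parameter))
    expect_equal(ct$df, (4 - 1) * 2)        # (I-1)J
  }
})

test_that("M2 reproduces the paired t-test exactly", {
  summ <- balanced_summary(13, I = 4, var_subject = 6, var_tech = 1,
                           tissue_effect = 2)
  fit <- fit_roi_model(summ, model_spec("M2"), features = summ$mz[1])
  ct <- contrast_test(fit, "B")
  sub <- summ[summ$condition == "A", ]
  w <- stats::reshape(sub[, c("subject", "tissue", "ybar")],
                      idvar = "subject", timevar = "tissue",
                      direction = "wide")
  tt <- stats::t.test(w$ybar.T1 - w$ybar.T2)
  expect_equal(ct$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(ct$p, tt$p.value, tolerance = 1e-10)
  expect_equal(ct$df, (4 - 1) * (2 - 1))    # (I-1)(K-1)
})

test_that("M3 exact dfs and Table-1 statistics from hand-set quantities", {
  summ <- balanced_summary(29, I = 4, var_subject = 2, var_tech = 1,
                           cond_effect = 3, tissue_effect = 2)
  fit <- fit_roi_model(summ, model_spec("M3"), features = summ$mz[1])
  ctA <- contrast_test(fit, "A")
  ctB <- contrast_test(fit, "B")
  ctC <- contrast_test(fit, "C")
  # df: B and C exact (I-1)J(K-1) = 6
  expect_equal(ctB$df, 6)
  expect_equal(ctC$df, 6)
  # hand evaluation of the balanced formulas from the fitted components
  cells <- tapply(summ$ybar, list(summ$condition, summ$tissue), mean)
  I <- 4
  expect_equal(ctA$estimate, cells["A", "T1"] - cells["B", "T1"],
               tolerance = 1e-10)
  expect_equal(ctA$se, sqrt(2 * (fit$sigma2_subj + fit$sigma2) / I),
               tolerance = 1e-12)
  expect_equal(ctB$se, sqrt(2 * fit$sigma2 / I), tolerance = 1e-12)
  expect_equal(ctC$se, sqrt(4 * fit$sigma2 / I), tolerance = 1e-12)
  expect_equal(ctB$estimate, cells["A", "T1"] - cells["A", "T2"],
               tolerance = 1e-10)
})

test_that("Satterthwaite df equals the two-mean-square closed form and is bracketed", {
  for (seed in 1:8) {
    summ <- balanced_summary(seed + 100, I = 4, var_subject = 3,
                             var_tech = 1)
    fit <- fit_roi_model(summ, model_spec("M3"), features = summ$mz[1])
    if (fit$singular) next
    ct <- contrast_test(fit, "A")
    ms <- fit$ms
    K <- 2
    df_closed <- (ms$ms_s + (K - 1) * ms$ms_r)^2 /
      (ms$ms_s^2 / ms$df_s + ((K - 1) * ms$ms_r)^2 / ms$df_r)
    expect_equal(ct$df, df_closed, tolerance = 1e-12)
    expect_gte(ct$df, min(ms$df_s, ms$df_r) - 1e-9)
    expect_lte(ct$df, ms$df_s + ms$df_r + 1e-9)
    expect_identical(ct$df_method, "satterthwaite")
  }
})

test_that("general-path Satterthwaite agrees with the balanced closed form", {
  # same balanced data routed through the delta-method path
  summ <- balanced_summary(55, I = 6, var_subject = 4, var_tech = 1)
  fit <- fit_roi_model(summ, model_spec("M3"), features = summ$mz[1])
  ct <- contrast_test(fit, "A")
  cl <- fit$cond_levels; tl <- fit$tissue_levels
  cvec <- msidiff:::cell_row("M3", cl, tl, 1, 1) -
    msidiff:::cell_row("M3", cl, tl, 2, 1)
  df_gen <- msidiff:::satterthwaite_df_general(fit$reml, cvec)
  expect_equal(df_gen, ct$df, tolerance = 0.05)
})

test_that("zero subject variance triggers the singular OLS fallback", {
  set.seed(77)
  n_sing <- 0
  for (f in 1:20) {
    summ <- balanced_summary(200 + f, I = 4, var_subject = 0, var_tech = 1)
    fit <- fit_roi_model(summ, model_spec("M3"), features = summ$mz[1])
    if (fit$singular) {
      n_sing <- n_sing + 1
      expect_identical(fit$method, "OLS-fallback")
      expect_identical(fit$sigma2_subj, 0)
      ct <- contrast_test(fit, "A")
      expect_equal(ct$df, fit$df_resid_ols)   # OLS df downstream
    }
  }
  expect_gte(n_sing, 8)                        # about half flag singular
})

test_that("variance-component recovery: mean sigma2_subj within 3 MC SE", {
  nf <- 400
  summ <- balanced_summary(303, I = 4, var_subject = 4, var_tech = 1,
                           n_features = nf)
  vc <- balanced_variance_components(summ)
  se <- stats::sd(vc$sigma2_subj) / sqrt(nf)
  expect_lt(abs(mean(vc$sigma2_subj) - 4), 3 * se)
  se2 <- stats::sd(vc$sigma2) / sqrt(nf)
  expect_lt(abs(mean(vc$sigma2) - 1), 3 * se2)
})

test_that("equal cell means give t = 0, p = 1", {
  summ <- balanced_summary(41, I = 4, var_subject = 1, var_tech = 1)
  summ$ybar <- 50                               # no variation at all
  fit <- fit_roi_model(summ, model_spec("M3"), features = summ$mz[1])
  ct <- contrast_test(fit, "A")
  expect_equal(ct$estimate, 0)
  expect_equal(ct$t, 0)
  expect_equal(ct$p, 1)
})

test_that("interaction-first flag fires when C is significant", {
  summ <- balanced_summary(47, I = 6, var_subject = 0.5, var_tech = 0.2,
                           inter_effect = 8)
  fit <- fit_roi_model(summ, model_spec("M3"), features = summ$mz[1])
  ctA <- contrast_test(fit, "A")
  expect_true(ctA$interaction_significant)
  ctC <- contrast_test(fit, "C")
  expect_lt(ctC$p, 0.05)
})

test_that("hypotheses are refused on models that cannot estimate them", {
  summ <- balanced_summary(53)
  f1 <- fit_roi_model(summ, model_spec("M1"), features = summ$mz[1])
  f2 <- fit_roi_model(summ, model_spec("M2"), features = summ$mz[1])
  expect_error(contrast_test(f1, "B"), "not estimable")
  expect_error(contrast_test(f2, "A"), "not estimable")
  expect_error(contrast_test(f1, "C"), "requires model M3")
})

test_that("pixel model with one pixel per ROI equals the ROI-mean model", {
  set.seed(61)
  runs <- list(); design <- NULL
  subj <- rep(sprintf("s%d", 1:8), each = 2)
  cond <- rep(c("A", "B"), each = 8)
  tiss <- rep(c("T1", "T2"), 8)
  vals <- stats::rnorm(16, 100, 5)
  for (i in 1:16) {
    id <- paste0(subj[i], "-", tiss[i])
    runs[[i]] <- msi_run(id, cbind(0L, 0L), 700, cbind(vals[i]))
  }
  e <- msi_experiment(runs, data.frame(
    run_id = vapply(runs, `[[`, character(1), "run_id"),
    subject = subj, condition = cond, tissue = tiss))
  masks <- stats::setNames(lapply(1:16, function(i)
    roi_mask("roi", "external")), names(e$runs))
  fpx <- fit_pixel_model(e, masks, spec = model_spec("M3", unit = "pixel"))
  summ <- summarize_roi_means(e, masks)
  froi <- fit_roi_model(summ, model_spec("M3"))
  expect_equal(fpx[[1]]$sigma2, froi[[1]]$sigma2, tolerance = 1e-6)
  expect_equal(fpx[[1]]$beta, froi[[1]]$beta, tolerance = 1e-8)
  expect_true(fpx[[1]]$pseudoreplicated)
  expect_false(froi[[1]]$pseudoreplicated)
})

test_that("diagnostics: calibration, outliers, heavy tails, short series", {
  # (a) iid Normal residuals pass >= 90% of the time at alpha_diag = 0.01
  set.seed(71)
  pass <- logical(200)
  for (i in 1:200) {
    summ <- balanced_summary(400 + i, I = 4, var_subject = 1, var_tech = 1)
    fit <- fit_roi_model(summ, model_spec("M3"), features = summ$mz[1])
    pass[i] <- model_diagnostics(fit)$pass
  }
  expect_gte(mean(pass), 0.9)
  # (b) a 10-SD outlier is flagged
  summ <- balanced_summary(88, I = 4, var_subject = 0, var_tech = 1)
  summ$ybar[3] <- summ$ybar[3] + 10 * stats::sd(summ$ybar)
  fit <- fit_roi_model(summ, model_spec("M3"), features = summ$mz[1])
  d <- model_diagnostics(fit)
  expect_gt(d$n_outliers, 0)
  expect_false(d$pass)
  # (c) heavy-tailed (t2) residuals fail normality far above alpha_diag
  set.seed(91)
  fails <- logical(100)
  for (i in 1:100) {
    summ <- balanced_summary(600 + i, I = 4, var_subject = 0, var_tech = 1)
    summ$ybar <- 100 + stats::rt(16, df = 2) * 3
    fit <- fit_roi_model(summ, model_spec("M3"), features = summ$mz[1])
    fails[i] <- !model_diagnostics(fit)$pass
  }
  expect_gt(mean(fails), 0.1)      # >> alpha_diag = 0.01
  # (d) < 8 residuals: not assessable, retained
  summ <- balanced_summary(99, I = 3)
  fit <- fit_roi_model(summ[summ$condition == "A", ], model_spec("M2"),
                       features = summ$mz[1])
  d <- model_diagnostics(fit)
  expect_false(d$assessable)
  expect_true(d$pass)
})

test_that("BH adjustment: hand case, degenerate cases, p.adjust oracle", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_identical(adjust_fdr(numeric(0)), numeric(0))
  set.seed(101)
  for (i in 1:10) {
    p <- stats::runif(50)^2
    p[sample(50, 5)] <- NA
    expect_equal(adjust_fdr(p), stats::p.adjust(p, "BH"))
  }
  # adjusted p >= p and monotone in p
  p <- stats::runif(100)
  a <- adjust_fdr(p)
  expect_true(all(a >= p - 1e-12))
  expect_true(all(diff(a[order(p)]) >= -1e-12))
})

test_that("test_features enforces the anti-leakage contract and per-family BH", {
  summ <- balanced_summary(111, I = 4, var_subject = 1, var_tech = 1,
                           n_features = 6)
  fits <- fit_roi_model(summ, model_spec("M3"))
  mzs <- unique(summ$mz)
  res <- test_features(fits, c("A", "B"), exclude_mz = mzs[1:2])
  expect_false(any(res$mz %in% mzs[1:2]))
  res_leak <- test_features(fits, c("A", "B"), exclude_mz = mzs[1:2],
                            allow_leakage = TRUE)
  expect_true(all(mzs %in% res_leak$mz))
  # BH applied within each hypothesis family separately
  for (h in c("A", "B")) {
    sel <- res$hypothesis == h & res$diagnostics_pass
    expect_equal(res$p_adj[sel], adjust_fdr(res$p[sel]))
  }
})
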