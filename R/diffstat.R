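# Step 3 + Step 4: ROI-mean summarization, per-feature linear mixed models,
# contrast tests with exact or Satterthwaite degrees of freedom, residual
# diagnostics and BH-FDR adjustment.

#' Summarize ROI mean intensities
#'
#' Averages each feature's intensity over the labelled ROI pixels of every
#' run, producing the modelling unit of the workflow: one row per
#' (feature, run, ROI) with the design factors attached. Zeros are included
#' in the mean (they are data under the zero-fill convention); set
#' `include_zeros = FALSE` to average nonzero pixels only.
#'
#' @param exp An [msi_experiment()].
#' @param masks Named list (by run id) of [roi_mask()]s; defaults to the
#'   experiment's own masks.
#' @param label ROI label to summarize (default `"roi"`).
#' @param include_zeros Include zero intensities in the mean (default TRUE).
#' @return A data frame of class `roi_summary` with columns `mz`, `run_id`,
#'   `subject`, `condition`, `tissue`, `roi`, `ybar`, `n_pixels`.
#' @export
summarize_roi_means <- function(exp, masks = exp$roi_masks, label = "roi",
                                include_zeros = TRUE) {
  stopifnot(inherits(exp, "msi_experiment"))
  if (is.null(masks)) stop("no ROI masks supplied")
  out <- vector("list", length(exp$runs))
  for (i in seq_along(exp$runs)) {
    run <- exp$runs[[i]]
    m <- masks[[run$run_id]]
    if (is.null(m)) stop("no mask for run ", run$run_id)
    sel <- m$labels == label
    if (!any(sel)) stop("run ", run$run_id, " has no pixels labelled '",
                        label, "'")
    sub <- run$intensities[sel, , drop = FALSE]
    if (include_zeros) {
      ybar <- colMeans(sub)
      npx <- rep(sum(sel), ncol(sub))
    } else {
      nz <- colSums(sub > 0)
      ybar <- ifelse(nz > 0, colSums(sub) / nz, 0)
      npx <- nz
    }
    d <- exp$design[i, ]
    out[[i]] <- data.frame(mz = run$mz, run_id = d$run_id,
                           subject = d$subject, condition = d$condition,
                           tissue = d$tissue, roi = label,
                           ybar = ybar, n_pixels = npx)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("roi_summary", "data.frame")
  res
}

#' Model specification for per-feature differential models
#'
#' The three observation-level models for a two-condition, two-tissue paired
#' design, on either ROI means or individual pixels:
#' * `M1` — subset to one tissue; one-way fixed-effect comparison of
#'   conditions (equivalent to a two-sample t-test on ROI means). The error
#'   term absorbs both between-subject and residual variance.
#' * `M2` — subset to one condition; fixed tissue effect plus a random
#'   subject intercept (equivalent to a paired t-test on ROI means).
#' * `M3` — all conditions and tissues: fixed condition, tissue and
#'   interaction effects (sum-to-zero coding) plus a random subject
#'   intercept. The recommended model.
#'
#' `unit = "pixel"` fits the analogous pixel-as-replicate models (the
#' pseudoreplication demonstration); their results are tagged
#' `pseudoreplicated`.
#'
#' @param model `"M1"`, `"M2"` or `"M3"`.
#' @param unit `"roi_mean"` (default) or `"pixel"`.
#' @param fix_level For M1/M2, the tissue (M1) or condition (M2) level to
#'   subset to; defaults to the first level alphabetically.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(model = c("M3", "M1", "M2"),
                       unit = c("roi_mean", "pixel"), fix_level = NULL) {
  model <- match.arg(model)
  unit <- match.arg(unit)
  structure(list(model = model, unit = unit, fix_level = fix_level),
            class = "model_spec")
}

# Build the cell-level fixed-effects design (sum-to-zero coding). Factors
# with a single observed level are dropped from the formula, so M3 on a
# single-tissue experiment degenerates to the condition-only model.
build_design <- function(df, model) {
  df$condition <- factor(df$condition)
  df$tissue <- factor(df$tissue)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  terms <- switch(model,
    M1 = "condition",
    M2 = "tissue",
    M3 = c("condition", "tissue"))
  terms <- terms[vapply(terms, function(t) nlevels(df[[t]]) >= 2,
                        logical(1))]
  if (length(terms) == 0L) {
    return(stats::model.matrix(~1, df))
  }
  form <- stats::as.formula(paste("~", paste(terms, collapse = " * ")))
  stats::model.matrix(form, df)
}

# Cell-mean design row for (condition level jc, tissue level kc).
cell_row <- function(model, cond_levels, tissue_levels, j, k) {
  df <- expand.grid(condition = factor(cond_levels, levels = cond_levels),
                    tissue = factor(tissue_levels, levels = tissue_levels))
  X <- build_design(df, model)
  X[df$condition == cond_levels[j] & df$tissue == tissue_levels[k], ,
    drop = FALSE][1, ]
}

check_balance <- function(df, model) {
  # complete crossing with exactly one observation per (subject, tissue)
  # and equal numbers of subjects per condition
  tab <- table(df$subject, df$tissue)
  if (any(tab != 1)) return(FALSE)
  subj_cond <- unique(df[, c("subject", "condition")])
  if (anyDuplicated(subj_cond$subject)) return(FALSE)  # subjects nested
  cnt <- table(subj_cond$condition)
  length(unique(cnt)) == 1L
}

# Balanced-ANOVA mean squares for the nested repeated-measures layout:
# MS_s (subjects within condition, averaged over tissues) and MS_r (the
# subject x tissue interaction residual).
balanced_ms <- function(df) {
  I <- length(unique(df$subject)) / length(unique(df$condition))
  J <- length(unique(df$condition))
  K <- length(unique(df$tissue))
  subj_mean <- tapply(df$ybar, df$subject, mean)
  cond_of_subj <- tapply(as.character(df$condition), df$subject, `[`, 1)
  cond_mean <- tapply(subj_mean, cond_of_subj, mean)
  ss_s <- K * sum((subj_mean - cond_mean[cond_of_subj])^2)
  df_s <- (I - 1) * J
  cell_mean <- tapply(df$ybar, list(df$condition, df$tissue), mean)
  resid <- df$ybar - subj_mean[as.character(df$subject)] -
    cell_mean[cbind(as.character(df$condition), as.character(df$tissue))] +
    cond_mean[as.character(df$condition)]
  ss_r <- sum(resid^2)
  df_r <- (I - 1) * J * (K - 1)
  list(ms_s = ss_s / df_s, ms_r = ss_r / df_r, df_s = df_s, df_r = df_r,
       I = I, J = J, K = K)
}

fit_one_feature <- function(df, spec) {
  model <- spec$model
  if (model == "M1") {
    lev <- spec$fix_level
    if (is.null(lev)) lev <- sort(unique(as.character(df$tissue)))[1]
    df <- df[df$tissue == lev, , drop = FALSE]
    random <- FALSE
  } else if (model == "M2") {
    lev <- spec$fix_level
    if (is.null(lev)) lev <- sort(unique(as.character(df$condition)))[1]
    df <- df[df$condition == lev, , drop = FALSE]
    random <- TRUE
  } else {
    random <- TRUE
  }
  df$condition <- factor(df$condition)
  df$tissue <- factor(df$tissue)
  if (model != "M2" && nlevels(df$condition) < 2) {
    stop("need >= 2 condition levels for model ", model)
  }
  cnt <- table(unique(df[, c("subject", "condition")])$condition)
  if (model != "M2" && any(cnt < 2)) {
    stop("inestimable: fewer than 2 subjects per condition")
  }

  # a subject with a single observation cannot separate subject variance
  # from residual variance; the random intercept is then unidentifiable and
  # is dropped (e.g. M3 on a single-tissue design)
  if (random && spec$unit == "roi_mean" && !any(duplicated(df$subject))) {
    random <- FALSE
  }
  X <- build_design(df, model)
  group <- if (random) df$subject else NULL
  balanced <- spec$unit == "roi_mean" && check_balance(df, model)
  ms <- if (balanced && model %in% c("M2", "M3") && random &&
            length(unique(df$tissue)) >= 2) balanced_ms(df) else NULL
  # for balanced data the ANOVA solution is the exact REML optimum; hand it
  # to the optimizer as a candidate so the equivalence holds to machine
  # precision rather than to optimizer tolerance
  lam_exact <- if (!is.null(ms) && ms$ms_r > 0) {
    (ms$ms_s - ms$ms_r) / (ms$K * ms$ms_r)
  } else NULL

  if (spec$unit == "pixel") {
    fit <- reml_fit_cells(s_cell = df$ybar * df$n_pixels,
                          q_cell = df$yss, n_cell = df$n_pixels,
                          X = X, group = group)
  } else {
    fit <- reml_fit_cells(s_cell = df$ybar, q_cell = df$ybar^2,
                          n_cell = rep(1, nrow(df)), X = X, group = group,
                          lambda_candidates = lam_exact)
  }

  # conditional (subject-level BLUP-adjusted) residuals at the cell level
  fitted_cell <- as.numeric(X %*% fit$beta)
  resid_cell <- df$ybar - fitted_cell
  if (!is.null(fit$blup)) {
    resid_cell <- resid_cell - fit$blup[as.character(df$subject)]
  }

  cond_levels <- levels(df$condition)
  tissue_levels <- levels(df$tissue)
  I_per_cond <- min(table(unique(df[, c("subject", "condition")])$condition))

  structure(list(
    spec = spec, model = model, data = df, X = X,
    beta = fit$beta, vcov_beta = fit$vcov_beta,
    sigma2 = fit$sigma2, sigma2_subj = fit$sigma2_subj,
    method = fit$method, singular = fit$singular,
    fitted = fitted_cell, residuals = resid_cell,
    n = fit$n, p = fit$p, df_resid_ols = fit$df_resid_ols,
    reml = fit, balanced = balanced, ms = ms,
    cond_levels = cond_levels, tissue_levels = tissue_levels,
    I = I_per_cond,
    J = length(cond_levels), K = length(tissue_levels),
    pseudoreplicated = spec$unit == "pixel"),
    class = "msidiff_fit")
}

#' Fit the per-feature ROI-mean model
#'
#' Fits the specified model independently to every feature of an ROI summary
#' by REML (profiled likelihood over the variance ratio). Singular fits
#' (between-subject variance estimated at the zero boundary) are refit
#' without the random effect and flagged; downstream tests then use the OLS
#' residual degrees of freedom.
#'
#' @param summary An `roi_summary` from [summarize_roi_means()].
#' @param spec A [model_spec()] with `unit = "roi_mean"`.
#' @param features Optional numeric vector of m/z values to fit (default all).
#' @return A list of `msidiff_fit` objects keyed by m/z (class
#'   `msidiff_fits`); if a single feature was requested, the fit itself.
#' @export
fit_roi_model <- function(summary, spec = model_spec("M3"), features = NULL) {
  stopifnot(inherits(summary, "roi_summary"))
  if (spec$unit != "roi_mean") stop("use fit_pixel_model for unit='pixel'")
  mzs <- if (is.null(features)) unique(summary$mz) else features
  fits <- lapply(mzs, function(f) {
    fit_one_feature(summary[summary$mz == f, , drop = FALSE], spec)
  })
  names(fits) <- format(mzs, trim = TRUE)
  if (length(fits) == 1L && !is.null(features) && length(features) == 1L) {
    return(fits[[1]])
  }
  structure(fits, class = "msidiff_fits", mz = mzs)
}

#' Fit pixel-as-replicate models (pseudoreplication demonstration)
#'
#' Fits the analogous models treating every labelled pixel as an independent
#' observation. Within-subject pairing is impossible at the pixel level, so
#' the M2 analogue reduces to a two-sample comparison. Results are tagged
#' `pseudoreplicated = TRUE`; these models are for the false-positive-rate
#' demonstration, not for inference.
#'
#' @param exp An [msi_experiment()].
#' @param masks,label ROI masks and label selecting the pixels.
#' @param spec A [model_spec()] with `unit = "pixel"`.
#' @param features Optional m/z subset.
#' @return As [fit_roi_model()].
#' @export
fit_pixel_model <- function(exp, masks = exp$roi_masks, label = "roi",
                            spec = model_spec("M3", unit = "pixel"),
                            features = NULL) {
  stopifnot(inherits(exp, "msi_experiment"))
  if (spec$unit != "pixel") stop("fit_pixel_model requires unit='pixel'")
  mz <- exp$runs[[1]]$mz
  cols <- if (is.null(features)) seq_along(mz) else
    vapply(features, function(f) feature_index(mz, f), integer(1))
  # per-run sufficient statistics per feature
  nr <- length(exp$runs)
  s_mat <- matrix(0, nr, length(cols))
  q_mat <- matrix(0, nr, length(cols))
  n_run <- integer(nr)
  for (i in seq_len(nr)) {
    run <- exp$runs[[i]]
    m <- masks[[run$run_id]]
    if (is.null(m)) stop("no mask for run ", run$run_id)
    sel <- m$labels == label
    if (!any(sel)) stop("run ", run$run_id, " has no pixels labelled '",
                        label, "'")
    sub <- run$intensities[sel, cols, drop = FALSE]
    s_mat[i, ] <- colSums(sub)
    q_mat[i, ] <- colSums(sub^2)
    n_run[i] <- sum(sel)
  }
  fits <- lapply(seq_along(cols), function(fi) {
    df <- data.frame(exp$design,
                     ybar = s_mat[, fi] / n_run,
                     yss = q_mat[, fi], n_pixels = n_run)
    fit_one_feature(df, spec)
  })
  names(fits) <- format(mz[cols], trim = TRUE)
  structure(fits, class = "msidiff_fits", mz = mz[cols])
}

feature_index <- function(mz_axis, f) {
  i <- which.min(abs(mz_axis - f))
  if (abs(mz_axis[i] - f) / f > 1e-6) {
    stop("feature m/z ", f, " not found on the axis")
  }
  as.integer(i)
}

#' Test a contrast on a fitted per-feature model
#'
#' Evaluates one of the standard hypotheses, or a custom coefficient vector,
#' on a fitted model:
#' * `"A"` — between-subject: condition 1 vs condition 2 within tissue 1.
#' * `"B"` — within-subject: tissue 1 vs tissue 2 within condition 1.
#' * `"C"` — interaction (difference of differences); requires M3.
#'
#' For balanced complete ROI-mean data the test statistic and degrees of
#' freedom follow the closed forms of the design: M1-A uses
#' `t = (Ybar11 - Ybar21)/sqrt(2(s2_subj + s2)/I)` with `(I-1)J` df (the
#' pooled two-sample t-test); M2-B and M3-B use `sqrt(2 s2 / I)` with exact
#' df; M3-A combines between- and within-subject mean squares and uses the
#' Satterthwaite approximation; M3-C uses `sqrt(4 s2 / I)`. Unbalanced data
#' and pixel models are routed to the general path (GLS contrast variance
#' plus delta-method Satterthwaite df). Singular fits use the OLS residual
#' df.
#'
#' When hypothesis A or B is requested from M3 the interaction (C) is
#' evaluated first; a significant interaction (p < 0.05) attaches a warning
#' flag, since main effects are then not interpretable on their own.
#'
#' @param fit An `msidiff_fit`.
#' @param hypothesis `"A"`, `"B"`, `"C"`, or a numeric contrast vector on the
#'   model coefficients.
#' @return A one-row data frame: estimate, SE, df, df method, t, p.
#' @export
contrast_test <- function(fit, hypothesis = "A") {
  stopifnot(inherits(fit, "msidiff_fit"))
  model <- fit$model
  cl <- fit$cond_levels; tl <- fit$tissue_levels
  custom <- is.numeric(hypothesis)

  if (!custom) {
    hyp <- match.arg(hypothesis, c("A", "B", "C"))
    if (hyp == "C" && model != "M3") {
      stop("hypothesis C (interaction) requires model M3")
    }
    if (hyp == "A" && model == "M2") {
      stop("hypothesis A is not estimable from M2 (single condition)")
    }
    if (hyp == "B" && model == "M1") {
      stop("hypothesis B is not estimable from M1 (single tissue)")
    }
    if (hyp %in% c("B", "C") && length(tl) < 2) {
      stop("hypothesis ", hyp, " is not estimable: single tissue level")
    }
    if (hyp %in% c("A", "C") && length(cl) < 2) {
      stop("hypothesis ", hyp, " is not estimable: single condition level")
    }
    cvec <- switch(hyp,
      A = cell_row(model, cl, tl, 1, 1) - cell_row(model, cl, tl, 2, 1),
      B = cell_row(model, cl, tl, 1, 1) - cell_row(model, cl, tl, 1, 2),
      C = cell_row(model, cl, tl, 1, 1) - cell_row(model, cl, tl, 1, 2) -
          cell_row(model, cl, tl, 2, 1) + cell_row(model, cl, tl, 2, 2))
  } else {
    hyp <- "custom"
    cvec <- hypothesis
    if (length(cvec) != length(fit$beta)) {
      stop("contrast vector length must match the number of coefficients")
    }
  }

  est <- sum(cvec * fit$beta)
  I <- fit$I
  use_closed <- fit$balanced && !custom && !fit$singular &&
    fit$spec$unit == "roi_mean" &&
    (model == "M1" || !is.null(fit$ms))

  if (use_closed) {
    if (model == "M1" && hyp == "A") {
      se <- sqrt(2 * fit$sigma2 / I)     # sigma2 here absorbs both components
      df <- (I - 1) * fit$J
      df_method <- "exact"
    } else if (model == "M2" && hyp == "B") {
      se <- sqrt(2 * fit$sigma2 / I)
      df <- (I - 1) * (fit$K - 1)
      df_method <- "exact"
    } else if (model == "M3" && hyp == "A") {
      se <- sqrt(2 * (fit$sigma2_subj + fit$sigma2) / I)
      ms <- fit$ms
      K <- fit$K
      num <- (ms$ms_s + (K - 1) * ms$ms_r)^2
      den <- ms$ms_s^2 / ms$df_s + ((K - 1) * ms$ms_r)^2 / ms$df_r
      df <- num / den
      df_method <- "satterthwaite"
    } else if (model == "M3" && hyp == "B") {
      se <- sqrt(2 * fit$sigma2 / I)
      df <- (I - 1) * fit$J * (fit$K - 1)
      df_method <- "exact"
    } else if (model == "M3" && hyp == "C") {
      se <- sqrt(4 * fit$sigma2 / I)
      df <- (I - 1) * fit$J * (fit$K - 1)
      df_method <- "exact"
    } else {
      use_closed <- FALSE
    }
  }
  if (!use_closed) {
    se <- sqrt(as.numeric(t(cvec) %*% fit$vcov_beta %*% cvec))
    if (fit$method == "REML") {
      df <- satterthwaite_df_general(fit$reml, cvec)
      df_method <- "satterthwaite"
    } else {
      df <- fit$df_resid_ols
      df_method <- "exact"
    }
  }

  t_stat <- if (se > 0) est / se else 0
  p <- if (se > 0) 2 * stats::pt(-abs(t_stat), df) else 1

  interaction_warning <- FALSE
  if (model == "M3" && hyp %in% c("A", "B") &&
      length(cl) >= 2 && length(tl) >= 2) {
    ct <- contrast_test_no_recurse(fit)
    interaction_warning <- is.finite(ct$p) && ct$p < 0.05
  }

  data.frame(hypothesis = hyp, estimate = est, se = se, df = df,
             df_method = df_method, t = t_stat, p = p,
             singular = fit$singular,
             pseudoreplicated = fit$pseudoreplicated,
             interaction_significant = interaction_warning)
}

# interaction test used internally by contrast_test (avoids infinite
# recursion when testing C itself)
contrast_test_no_recurse <- function(fit) {
  cl <- fit$cond_levels; tl <- fit$tissue_levels
  cvec <- cell_row("M3", cl, tl, 1, 1) - cell_row("M3", cl, tl, 1, 2) -
    cell_row("M3", cl, tl, 2, 1) + cell_row("M3", cl, tl, 2, 2)
  est <- sum(cvec * fit$beta)
  if (fit$balanced && !fit$singular) {
    se <- sqrt(4 * fit$sigma2 / fit$I)
    df <- (fit$I - 1) * fit$J * (fit$K - 1)
  } else {
    se <- sqrt(as.numeric(t(cvec) %*% fit$vcov_beta %*% cvec))
    df <- if (fit$method == "REML") {
      satterthwaite_df_general(fit$reml, cvec)
    } else fit$df_resid_ols
  }
  t_stat <- if (se > 0) est / se else 0
  list(t = t_stat, p = if (se > 0) 2 * stats::pt(-abs(t_stat), df) else 1)
}

#' Residual diagnostics for a fitted model
#'
#' Evaluates (a) residual normality (Shapiro-Wilk), (b) homogeneity of
#' variance across condition-by-tissue cells (Levene-type ANOVA of absolute
#' deviations from cell medians), and (c) studentized-residual outliers at
#' `|r| > 3`. Features failing any check at `alpha_diag` are flagged for
#' exclusion from inference. Fewer than 8 residuals: diagnostics are
#' reported as not assessable and the feature is retained with a warning
#' flag.
#'
#' @param fit An `msidiff_fit`.
#' @param alpha_diag Significance level for the diagnostic tests (0.01).
#' @return A one-row data frame with the test statistics, p-values, outlier
#'   count and overall `pass`.
#' @export
model_diagnostics <- function(fit, alpha_diag = 0.01) {
  r <- fit$residuals
  n <- length(r)
  if (n < 8) {
    return(data.frame(normality_p = NA_real_, levene_p = NA_real_,
                      n_outliers = NA_integer_, assessable = FALSE,
                      pass = TRUE))
  }
  sw <- stats::shapiro.test(r)
  cells <- interaction(fit$data$condition, fit$data$tissue, drop = TRUE)
  lev_p <- NA_real_
  if (nlevels(cells) >= 2 && all(table(cells) >= 2)) {
    med <- tapply(r, cells, stats::median)
    ad <- abs(r - med[cells])
    lev <- stats::anova(stats::lm(ad ~ cells))
    lev_p <- lev$`Pr(>F)`[1]
  }
  # studentized residuals via the fixed-effects hat matrix
  X <- fit$X
  h <- diag(X %*% solve(crossprod(X), t(X)))
  s <- sqrt(sum(r^2) / max(1, n - fit$p))
  stud <- r / (s * sqrt(pmax(1 - h, 1e-8)))
  n_out <- sum(abs(stud) > 3)
  pass <- (sw$p.value > alpha_diag) &&
    (is.na(lev_p) || lev_p > alpha_diag) && n_out == 0
  data.frame(normality_p = sw$p.value, levene_p = lev_p,
             n_outliers = n_out, assessable = TRUE, pass = pass)
}

#' Balanced-ANOVA variance components per feature
#'
#' Method-of-moments estimates from the balanced nested repeated-measures
#' mean squares: `sigma2 = MS_resid` and
#' `sigma2_subj = (MS_subject - MS_resid) / K`. Unlike the REML fit these
#' are left untruncated at zero (`truncate = FALSE`), which keeps the
#' across-feature average unbiased — the property needed when summarizing
#' variance-ratio structure over many features.
#'
#' @param summary An `roi_summary` with balanced complete data.
#' @param truncate Truncate negative subject-variance estimates at 0.
#' @return Data frame `(mz, sigma2_subj, sigma2)`.
#' @export
balanced_variance_components <- function(summary, truncate = FALSE) {
  stopifnot(inherits(summary, "roi_summary"))
  mzs <- unique(summary$mz)
  out <- lapply(mzs, function(f) {
    df <- summary[summary$mz == f, , drop = FALSE]
    if (!check_balance(df, "M3")) {
      stop("balanced closed forms require balanced complete data")
    }
    ms <- balanced_ms(df)
    vs <- (ms$ms_s - ms$ms_r) / ms$K
    if (truncate) vs <- max(0, vs)
    data.frame(mz = f, sigma2_subj = vs, sigma2 = ms$ms_r)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: monotone, capped at 1; `NA`/`NaN` inputs are
#' propagated and excluded from the number of tests.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
adjust_fdr <- function(pvalues) {
  out <- rep(NA_real_, length(pvalues))
  ok <- which(!is.na(pvalues))
  m <- length(ok)
  if (m == 0L) return(out)
  p <- pvalues[ok]
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * m / rev(seq_len(m))))
  out[ok[o]] <- adj
  out
}

#' Contrast tests across all fitted features
#'
#' Runs [contrast_test()] for every fit, applies [model_diagnostics()], and
#' BH-adjusts p-values separately per hypothesis family. Features whose m/z
#' appears in `exclude_mz` (typically the segmentation-consumed features) are
#' refused unless `allow_leakage = TRUE`; diagnostics failures are excluded
#' from adjustment unless `exclude_failing = FALSE`.
#'
#' @param fits An `msidiff_fits` list.
#' @param hypotheses Character vector of hypothesis ids.
#' @param exclude_mz m/z values excluded from testing (anti-leakage rule).
#' @param allow_leakage Test consumed features anyway (default FALSE).
#' @param run_diagnostics Apply residual diagnostics (default TRUE).
#' @param exclude_failing Drop diagnostics-failing features from adjusted
#'   inference (their unadjusted results are still reported).
#' @return Data frame with one row per (feature, hypothesis).
#' @export
test_features <- function(fits, hypotheses = c("A", "B"),
                          exclude_mz = NULL, allow_leakage = FALSE,
                          run_diagnostics = TRUE, exclude_failing = TRUE) {
  stopifnot(inherits(fits, "msidiff_fits"))
  mzs <- attr(fits, "mz")
  keep <- rep(TRUE, length(mzs))
  if (!is.null(exclude_mz) && !allow_leakage) {
    keep <- !vapply(mzs, function(m) {
      any(abs(exclude_mz - m) / m < 1e-6)
    }, logical(1))
  }
  rows <- list()
  for (i in which(keep)) {
    fit <- fits[[i]]
    diag <- if (run_diagnostics) model_diagnostics(fit) else
      data.frame(pass = TRUE, assessable = FALSE)
    for (h in hypotheses) {
      ct <- contrast_test(fit, h)
      ct$mz <- mzs[i]
      ct$diagnostics_pass <- diag$pass
      rows[[length(rows) + 1L]] <- ct
    }
  }
  res <- do.call(rbind, rows)
  res <- res[, c("mz", setdiff(names(res), "mz"))]
  res$p_adj <- NA_real_
  for (h in unique(res$hypothesis)) {
    sel <- res$hypothesis == h &
      (!exclude_failing | res$diagnostics_pass)
    res$p_adj[sel] <- adjust_fdr(res$p[sel])
  }
  rownames(res) <- NULL
  res
}
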