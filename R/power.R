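# Step 5: model-based planning of future experiments. Replicate numbers and
# minimum detectable differences follow from bounding the standard error of
# the contrast by Delta / (z_{1-alpha/2} + z_{1-beta}); with FDR control the
# per-test alpha is replaced by the average alpha implied by the target FDR.

#' Bundle power-calculation inputs
#'
#' @param delta Smallest difference to detect, in intensity units (or in %
#'   of `baseline` when `percent = TRUE`).
#' @param alpha Per-test significance level; ignored when `q` is given.
#' @param q Target FDR; when non-NULL, `alpha` is replaced by
#'   [fdr_average_alpha()] using `beta` and `m0_over_m1`.
#' @param beta Tolerated type-II error (1 - power).
#' @param m0_over_m1 Expected ratio of null to differential features.
#' @param var_subject,var_tech Variance components (sigma2_subj, sigma2),
#'   typically the median (or 75th percentile, for a conservative estimate)
#'   over features of a fitted collection.
#' @param hypothesis `"A"` (between-subject: variance sigma2_subj + sigma2)
#'   or `"B"` (within-subject: subject variance cancels, sigma2 only).
#' @return An object of class `power_spec`.
#' @export
power_spec <- function(delta = NULL, alpha = 0.05, q = NULL, beta = 0.1,
                       m0_over_m1 = 9, var_subject = 1, var_tech = 1,
                       hypothesis = c("A", "B")) {
  hypothesis <- match.arg(hypothesis)
  if (!is.null(delta) && delta <= 0) stop("delta must be > 0")
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1) {
    stop("alpha and beta must be in (0, 1)")
  }
  if (!is.null(q) && (q <= 0 || q >= 1)) stop("q must be in (0, 1)")
  if (m0_over_m1 < 0) stop("m0_over_m1 must be >= 0")
  if (var_subject < 0 || var_tech < 0) stop("variances must be >= 0")
  structure(list(delta = delta, alpha = alpha, q = q, beta = beta,
                 m0_over_m1 = m0_over_m1, var_subject = var_subject,
                 var_tech = var_tech, hypothesis = hypothesis),
            class = "power_spec")
}

#' Average per-test significance level under FDR control
#'
#' `alpha_ave = (1 - beta_ave) * q / (1 + (1 - q) * m0/m1)`: the per-test
#' level at which Benjamini-Hochberg control of the FDR at `q` is expected
#' to operate, given the anticipated average power `1 - beta_ave` and the
#' ratio of null to differential features.
#'
#' @param q Target FDR in (0, 1).
#' @param beta_ave Anticipated average type-II error in (0, 1).
#' @param m0_over_m1 Null-to-differential feature ratio (>= 0).
#' @return The average alpha (scalar).
#' @export
fdr_average_alpha <- function(q, beta_ave, m0_over_m1) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  if (beta_ave < 0 || beta_ave >= 1) stop("beta_ave must be in [0, 1)")
  if (m0_over_m1 < 0) stop("m0_over_m1 must be >= 0")
  (1 - beta_ave) * q / (1 + (1 - q) * m0_over_m1)
}

effective_alpha <- function(spec) {
  if (!is.null(spec$q)) {
    fdr_average_alpha(spec$q, spec$beta, spec$m0_over_m1)
  } else {
    spec$alpha
  }
}

contrast_variance <- function(spec) {
  if (spec$hypothesis == "A") spec$var_subject + spec$var_tech else
    spec$var_tech
}

#' Biological replicates required per condition
#'
#' Smallest integer `I` with
#' `I >= 2 ((z_{1-alpha/2} + z_{1-beta}) / delta)^2 V`, where `V` is
#' `sigma2_subj + sigma2` for between-subject comparisons and `sigma2` for
#' within-subject ones (the subject variance cancels when each subject is
#' its own control). With `q` set, `alpha` is the FDR-implied average alpha.
#' Standard Normal quantiles are used, as in the printed formula; `t_refine`
#' iterates with t quantiles at the design's df instead.
#'
#' @param spec A [power_spec()] with `delta` set.
#' @param t_refine Iterate with t quantiles (default FALSE).
#' @return Integer `I >= 2`. When the variance is zero the floor of 2 is
#'   returned with attribute `note`.
#' @export
required_replicates <- function(spec, t_refine = FALSE) {
  stopifnot(inherits(spec, "power_spec"))
  if (is.null(spec$delta)) stop("spec$delta is required")
  V <- contrast_variance(spec)
  alpha <- effective_alpha(spec)
  if (V == 0) {
    I <- 2L
    attr(I, "note") <- "zero variance: any I >= 2 meets the bound"
    return(I)
  }
  zsum <- stats::qnorm(1 - alpha / 2) + stats::qnorm(1 - spec$beta)
  # tiny slack keeps exact-boundary inputs (e.g. delta = MDD(I)) from being
  # pushed up one replicate by floating-point noise
  I <- max(2L, as.integer(ceiling(2 * (zsum / spec$delta)^2 * V - 1e-9)))
  if (t_refine) {
    repeat {
      df <- max(1, 2 * (I - 1))   # two-group design df at current I
      tsum <- stats::qt(1 - alpha / 2, df) + stats::qt(1 - spec$beta, df)
      I2 <- max(2L, as.integer(ceiling(2 * (tsum / spec$delta)^2 * V)))
      if (I2 <= I) break
      I <- I2
    }
  }
  I
}

#' Minimum detectable difference at a fixed replicate number
#'
#' Inverts the sample-size bound: `delta = (z_{1-alpha/2} + z_{1-beta}) *
#' sqrt(2 V / I)`. Optionally expressed as a percent of a supplied baseline
#' mean.
#'
#' @param I Biological replicates per condition (>= 2).
#' @param spec A [power_spec()] (its `delta` is ignored).
#' @param baseline Optional reference mean intensity; when given, the MDD is
#'   also returned as a percentage of it.
#' @return Named numeric: `delta` (and `delta_pct` when `baseline` given).
#' @export
minimum_detectable_difference <- function(I, spec, baseline = NULL) {
  stopifnot(inherits(spec, "power_spec"))
  if (I < 2) stop("I must be >= 2")
  V <- contrast_variance(spec)
  alpha <- effective_alpha(spec)
  zsum <- stats::qnorm(1 - alpha / 2) + stats::qnorm(1 - spec$beta)
  delta <- zsum * sqrt(2 * V / I)
  out <- c(delta = delta)
  if (!is.null(baseline)) out <- c(out, delta_pct = 100 * delta / baseline)
  out
}

#' Replicate-requirement curves over a grid of detectable differences
#'
#' Tabulates [required_replicates()] over percent differences, hypotheses
#' A/B, correction choices (none vs FDR) and null ratios, for planning plots.
#'
#' @param spec A [power_spec()] carrying alpha/q/beta and the variance
#'   components; its `delta` and `hypothesis` are ignored.
#' @param delta_pct_grid Percent differences to scan.
#' @param baseline Reference mean converting percent to intensity units.
#' @param m0_over_m1_grid Null ratios for the FDR curves (default `c(1, 9)`).
#' @return Data frame `(hypothesis, correction, m0_over_m1, delta_pct, I)`.
#' @export
power_curve <- function(spec, delta_pct_grid, baseline,
                        m0_over_m1_grid = c(1, 9)) {
  stopifnot(inherits(spec, "power_spec"), length(delta_pct_grid) >= 1)
  rows <- list()
  for (hyp in c("A", "B")) {
    for (corr in c("none", "FDR")) {
      ratios <- if (corr == "FDR") m0_over_m1_grid else NA
      for (r in ratios) {
        for (dp in delta_pct_grid) {
          s <- spec
          s$hypothesis <- hyp
          s$delta <- dp / 100 * baseline
          if (corr == "FDR") {
            if (is.null(s$q)) s$q <- 0.05
            s$m0_over_m1 <- r
          } else {
            s$q <- NULL
          }
          rows[[length(rows) + 1L]] <- data.frame(
            hypothesis = hyp, correction = corr, m0_over_m1 = r,
            delta_pct = dp, I = required_replicates(s))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median variance components from a fitted collection
#'
#' Summarizes sigma2_subj and sigma2 across per-feature fits, the inputs the
#' planning formulas expect; `probs = 0.75` gives the conservative variant.
#'
#' @param fits An `msidiff_fits` list.
#' @param probs Quantile to take across features (default 0.5, the median).
#' @return Named numeric `c(var_subject, var_tech)`.
#' @export
variance_component_summary <- function(fits, probs = 0.5) {
  vs <- vapply(fits, function(f) f$sigma2_subj, numeric(1))
  ve <- vapply(fits, function(f) f$sigma2, numeric(1))
  c(var_subject = stats::quantile(vs, probs, names = FALSE),
    var_tech = stats::quantile(ve, probs, names = FALSE))
}
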