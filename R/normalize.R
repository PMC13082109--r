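# Between-run normalization and sparsity accounting.

#' Censored-median between-run normalization
#'
#' Robust global normalization for sparse, outlier-heavy peak-picked data.
#' Per run: (a) collect the nonzero intensities (sparse zeros dropped),
#' optionally restricted to pixels outside `exclude_labels`; (b) right-censor
#' at the `censor_q` quantile — by default values above the threshold are
#' clamped to it (censoring retains the observation at the bound;
#' `censor = "drop"` deletes them instead); (c) the run constant is the
#' median of the censored values. Every intensity in the run is then scaled
#' by `pooled_median / run_constant`, where the pooled median is the median
#' of all runs' censored nonzero values pooled (or the median of run
#' constants with `pooling = "median_of_medians"`). Zeros stay zero.
#'
#' The procedure is idempotent and scale-equivariant: applying it twice
#' equals applying it once, and pre-multiplying one run by a constant does
#' not change the output.
#'
#' @param exp An [msi_experiment()].
#' @param censor_q Censoring quantile in (0, 1); default 0.95. Quantiles use
#'   linear interpolation between order statistics (type 7).
#' @param exclude_labels ROI labels whose pixels are ignored when computing
#'   the constants (e.g. `"background"`); needs `masks`.
#' @param masks Optional named list of [roi_mask()]s (defaults to the
#'   experiment's own).
#' @param censor `"clamp"` (default) or `"drop"`.
#' @param pooling `"pooled"` (default) or `"median_of_medians"`.
#' @return List with `experiment` (normalized) and `report` (per-run
#'   threshold, constant and scale factor, plus the pooled median).
#' @export
censored_median_normalize <- function(exp, censor_q = 0.95,
                                      exclude_labels = "background",
                                      masks = exp$roi_masks,
                                      censor = c("clamp", "drop"),
                                      pooling = c("pooled",
                                                  "median_of_medians")) {
  stopifnot(inherits(exp, "msi_experiment"))
  censor <- match.arg(censor)
  pooling <- match.arg(pooling)
  if (censor_q <= 0 || censor_q >= 1) stop("censor_q must be in (0, 1)")

  censored_values <- function(run) {
    ints <- run$intensities
    if (!is.null(masks) && !is.null(masks[[run$run_id]]) &&
        length(exclude_labels)) {
      keep <- !(masks[[run$run_id]]$labels %in% exclude_labels)
      ints <- ints[keep, , drop = FALSE]
    }
    v <- ints[ints > 0]
    if (length(v) == 0L) {
      stop("run ", run$run_id, " has no nonzero intensities")
    }
    thr <- stats::quantile(v, censor_q, names = FALSE, type = 7)
    v <- if (censor == "clamp") pmin(v, thr) else v[v <= thr]
    list(values = v, threshold = thr)
  }

  cens <- lapply(exp$runs, censored_values)
  run_constant <- vapply(cens, function(z) stats::median(z$values), numeric(1))
  pooled <- if (pooling == "pooled") {
    stats::median(unlist(lapply(cens, `[[`, "values")))
  } else {
    stats::median(run_constant)
  }
  scale <- pooled / run_constant

  runs <- exp$runs
  for (i in seq_along(runs)) {
    runs[[i]]$intensities <- runs[[i]]$intensities * scale[i]
  }
  report <- data.frame(run_id = names(exp$runs),
                       threshold = vapply(cens, `[[`, numeric(1), "threshold"),
                       run_constant = run_constant,
                       scale = scale, pooled_median = pooled)
  rownames(report) <- NULL
  list(experiment = msi_experiment(runs, exp$design, exp$roi_masks),
       report = report)
}

#' Global pixel-wise normalization (TIC / RMS / reference)
#'
#' Divides each pixel's intensities by a pixel constant — the total ion
#' current (`tic`), the root mean square (`rms`), or the intensity of a
#' spiked reference feature (`reference`) — then rescales by the
#' experiment-wide mean constant so the overall intensity scale is
#' preserved. Pixels with a zero constant are left unchanged and their count
#' is reported.
#'
#' @param exp An [msi_experiment()].
#' @param method `"tic"`, `"rms"` or `"reference"`.
#' @param ref_feature m/z of the reference feature (required for
#'   `method = "reference"`; must be on the axis).
#' @return List with `experiment` and `report` (per run: mean constant,
#'   number of zero-constant pixels).
#' @export
global_normalize <- function(exp, method = c("tic", "rms", "reference"),
                             ref_feature = NULL) {
  stopifnot(inherits(exp, "msi_experiment"))
  method <- match.arg(method)
  mz <- exp$runs[[1]]$mz
  ref_col <- NULL
  if (method == "reference") {
    if (is.null(ref_feature)) stop("method='reference' needs ref_feature")
    ref_col <- feature_index(mz, ref_feature)
  }
  const_list <- lapply(exp$runs, function(run) {
    switch(method,
           tic = rowSums(run$intensities),
           rms = sqrt(rowMeans(run$intensities^2)),
           reference = run$intensities[, ref_col])
  })
  all_const <- unlist(const_list)
  mean_const <- mean(all_const[all_const > 0])
  runs <- exp$runs
  report <- data.frame(run_id = names(runs),
                       n_zero_constant = vapply(const_list,
                                                function(v) sum(v == 0),
                                                integer(1)),
                       mean_constant = mean_const)
  for (i in seq_along(runs)) {
    cst <- const_list[[i]]
    f <- ifelse(cst > 0, mean_const / cst, 1)
    runs[[i]]$intensities <- runs[[i]]$intensities * f
  }
  rownames(report) <- NULL
  list(experiment = msi_experiment(runs, exp$design, exp$roi_masks),
       report = report)
}

#' Per-feature sparsity within a labelled ROI
#'
#' Fraction of labelled pixels at which each feature is zero (absent peak),
#' per run.
#'
#' @param exp An [msi_experiment()].
#' @param masks Named list of [roi_mask()]s.
#' @param label ROI label (must be present in every run's mask).
#' @return Numeric matrix, runs x features.
#' @export
feature_sparsity <- function(exp, masks = exp$roi_masks, label = "roi") {
  stopifnot(inherits(exp, "msi_experiment"))
  if (is.null(masks)) stop("no masks supplied")
  out <- t(vapply(exp$runs, function(run) {
    m <- masks[[run$run_id]]
    if (is.null(m)) stop("no mask for run ", run$run_id)
    sel <- m$labels == label
    if (!any(sel)) stop("label '", label, "' absent from mask of run ",
                        run$run_id)
    colMeans(run$intensities[sel, , drop = FALSE] == 0)
  }, numeric(length(exp$runs[[1]]$mz))))
  rownames(out) <- names(exp$runs)
  out
}
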