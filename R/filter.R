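# Step 2: non-specific filtering, ROI-sparsity filtering, clustering of
# related features (isotopes) and aggregation to representative features.
# All operations are blinded to the condition labels, and a FeatureStatus
# ledger accounts for every feature: n_retained plus the per-reason drop
# counts always sum to the input feature count.

#' Initialize the per-feature status ledger
#'
#' One row per feature with its summary statistics (mean and SD over pooled
#' non-background, nonzero pixels across runs) and bookkeeping fields used by
#' the Step-2 filters.
#'
#' @param exp An [msi_experiment()].
#' @param masks Optional masks; `background`-labelled pixels are excluded
#'   from the summary statistics.
#' @return Data frame of class `feature_status`.
#' @export
feature_status_init <- function(exp, masks = exp$roi_masks) {
  mz <- exp$runs[[1]]$mz
  pooled <- do.call(rbind, lapply(exp$runs, function(run) {
    ints <- run$intensities
    if (!is.null(masks) && !is.null(masks[[run$run_id]])) {
      ints <- ints[masks[[run$run_id]]$labels != "background", , drop = FALSE]
    }
    ints
  }))
  mean_nz <- numeric(length(mz)); sd_nz <- numeric(length(mz))
  for (f in seq_along(mz)) {
    v <- pooled[, f]; v <- v[v > 0]
    mean_nz[f] <- if (length(v)) mean(v) else 0
    sd_nz[f] <- if (length(v) > 1) stats::sd(v) else 0
  }
  st <- data.frame(feature = seq_along(mz), mz = mz,
                   mean = mean_nz, sd = sd_nz,
                   max_roi_sparsity = NA_real_,
                   cluster_id = 0L, representative = TRUE,
                   retained = TRUE, drop_reason = "none",
                   stringsAsFactors = FALSE)
  class(st) <- c("feature_status", "data.frame")
  st
}

drop_features <- function(status, idx, reason) {
  idx <- idx[status$retained[idx]]
  status$retained[idx] <- FALSE
  status$drop_reason[idx] <- reason
  status
}

#' Exclude segmentation-consumed features from the testable set
#'
#' Enforces the anti-double-dipping rule: features whose intensities were
#' used to build any data-driven ROI mask are removed from downstream
#' differential testing.
#'
#' @param status A `feature_status`.
#' @param masks Named list of [roi_mask()]s (or a numeric vector of m/z).
#' @return Updated status.
#' @export
mark_consumed <- function(status, masks) {
  consumed <- if (is.numeric(masks)) masks else features_consumed(masks)
  if (length(consumed) == 0L) return(status)
  hit <- vapply(status$mz, function(m) {
    any(abs(consumed - m) / m < 1e-6)
  }, logical(1))
  drop_features(status, which(hit), "consumed_by_segmentation")
}

#' Non-specific (blinded) low-signal filter
#'
#' Drops features whose pooled nonzero mean AND standard deviation both fall
#' strictly below the `q`-th percentile of all features' means and SDs.
#' Condition labels are never consulted.
#'
#' @param status A `feature_status` (percentiles are computed over all its
#'   features, dropped or not).
#' @param q Percentile in `[0, 1)`; default 0.25.
#' @return Updated status.
#' @export
nonspecific_filter <- function(status, q = 0.25) {
  if (q < 0 || q >= 1) stop("q must be in [0, 1)")
  if (q == 0) return(status)
  qm <- stats::quantile(status$mean, q, names = FALSE, type = 7)
  qs <- stats::quantile(status$sd, q, names = FALSE, type = 7)
  low <- which(status$mean < qm & status$sd < qs)
  out <- drop_features(status, low, "low_signal")
  if (!any(out$retained)) {
    stop("non-specific filter removed every feature; lower q")
  }
  out
}

#' ROI sparsity filter (any-run rule)
#'
#' Drops a feature when its sparsity (fraction of zero pixels) inside the
#' labelled ROI exceeds `max_sparsity` in ANY single run. The threshold is a
#' strict inequality ("more than"), so a feature exactly at the bound is
#' retained.
#'
#' @param exp An [msi_experiment()].
#' @param status A `feature_status`.
#' @param masks,label ROI masks and label (see [feature_sparsity()]).
#' @param max_sparsity Maximum tolerated per-run ROI sparsity; default 0.25.
#' @return Updated status (with `max_roi_sparsity` filled in).
#' @export
roi_sparsity_filter <- function(exp, status, masks = exp$roi_masks,
                                label = "roi", max_sparsity = 0.25) {
  sp <- feature_sparsity(exp, masks, label)
  status$max_roi_sparsity <- apply(sp, 2, max)
  drop_features(status, which(status$max_roi_sparsity > max_sparsity),
                "high_sparsity")
}

#' Cluster related features (isotope envelopes)
#'
#' Builds a graph over retained features with an edge whenever two features
#' are separated by 1-3 times the isotope spacing (1.00336 Da, the 13C-12C
#' mass difference, singly charged) within a ppm tolerance AND their ion
#' images are spatially similar (cosine or Pearson over pooled
#' non-background pixels of all runs). Connected components become clusters;
#' isolated features keep `cluster_id = 0`.
#'
#' @param exp An [msi_experiment()].
#' @param status A `feature_status`.
#' @param masks Optional masks (background excluded from similarity).
#' @param mass_delta Isotope spacing in Da.
#' @param mass_tol_ppm Mass-difference tolerance in ppm.
#' @param min_similarity Minimum spatial similarity for an edge.
#' @param metric `"cosine"` (default) or `"pearson"`.
#' @param max_n Highest isotope index considered (default 3).
#' @return Updated status with `cluster_id` assigned.
#' @export
cluster_related_features <- function(exp, status, masks = exp$roi_masks,
                                     mass_delta = 1.00336,
                                     mass_tol_ppm = 20,
                                     min_similarity = 0.7,
                                     metric = c("cosine", "pearson"),
                                     max_n = 3) {
  metric <- match.arg(metric)
  keep <- which(status$retained)
  mz <- status$mz[keep]
  pooled <- do.call(rbind, lapply(exp$runs, function(run) {
    ints <- run$intensities[, status$feature[keep], drop = FALSE]
    if (!is.null(masks) && !is.null(masks[[run$run_id]])) {
      ints <- ints[masks[[run$run_id]]$labels != "background", , drop = FALSE]
    }
    ints
  }))
  m <- length(keep)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  sim_fun <- function(a, b) {
    if (metric == "cosine") {
      den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
      if (den == 0) 0 else sum(a * b) / den
    } else {
      if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(a, b)
    }
  }
  for (i in seq_len(m)) {
    for (nn in seq_len(max_n)) {
      target <- mz[i] + nn * mass_delta
      tol <- mass_tol_ppm * 1e-6 * target
      js <- which(abs(mz - target) <= tol)
      for (j in js) {
        if (sim_fun(pooled[, i], pooled[, j]) >= min_similarity) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  comp_size <- table(roots)
  cluster_id <- integer(m)
  next_id <- 1L
  for (r in names(comp_size)[comp_size > 1]) {
    cluster_id[roots == as.integer(r)] <- next_id
    next_id <- next_id + 1L
  }
  status$cluster_id[keep] <- cluster_id
  status
}

#' Aggregate feature clusters to representatives
#'
#' Within each cluster the member with the highest mean intensity becomes the
#' representative (the most intense peak of the isotope envelope, usually
#' the monoisotopic one); ties break toward the lower m/z. Other members are
#' dropped as `non_representative`. Aggregation never invents intensities:
#' the reduced experiment is a column subset of the input.
#'
#' @param exp An [msi_experiment()].
#' @param status A `feature_status` with `cluster_id` assigned.
#' @return List with `experiment` (reduced to retained features) and
#'   `status`.
#' @export
aggregate_clusters <- function(exp, status) {
  for (cid in setdiff(unique(status$cluster_id), 0L)) {
    members <- which(status$cluster_id == cid & status$retained)
    if (length(members) < 2L) next
    best <- members[order(-status$mean[members], status$mz[members])][1]
    status$representative[setdiff(members, best)] <- FALSE
    status <- drop_features(status, setdiff(members, best),
                            "non_representative")
  }
  keep_cols <- status$feature[status$retained]
  runs <- lapply(exp$runs, function(run) {
    msi_run(run$run_id, run$coords, run$mz[keep_cols],
            run$intensities[, keep_cols, drop = FALSE])
  })
  list(experiment = msi_experiment(runs, exp$design, exp$roi_masks),
       status = status)
}

#' Feature-count ledger
#'
#' Fig-8A-style accounting: the retained count plus the per-reason drop
#' counts, which always sum to the number of input features.
#'
#' @param status A `feature_status`.
#' @return Data frame `(stage, n)`.
#' @export
status_ledger <- function(status) {
  reasons <- c("consumed_by_segmentation", "low_signal", "high_sparsity",
               "non_representative")
  counts <- vapply(reasons, function(r) sum(status$drop_reason == r),
                   integer(1))
  data.frame(stage = c("input", reasons, "retained"),
             n = c(nrow(status), counts, sum(status$retained)))
}
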