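# End-to-end pipeline driver and the two simulation studies used to validate
# the workflow's operating characteristics.

default_workflow_config <- function() {
  list(
    seed = 1,
    normalize = list(method = "censored-median", censor_q = 0.95),
    segment = list(method = "truth"),     # truth | none | gmm (marker mz, k)
    filter = list(nonspecific_q = 0.25, max_roi_sparsity = 0.25,
                  cluster = TRUE, mass_tol_ppm = 20, min_similarity = 0.7),
    test = list(model = "M3", hypotheses = c("A", "B"), fdr = 0.05,
                roi_label = "roi", allow_leakage = FALSE),
    power = list(beta = 0.1, q = 0.05, m0_over_m1 = 9,
                 delta_pct_grid = c(10, 20, 30, 50, 100))
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the five-step differential-analysis workflow
#'
#' Executes normalize -> segment -> filter -> test -> power on an experiment
#' (or a named simulation preset), writing per-stage CSV outputs and a
#' provenance log to `out_dir`. The anti-leakage contract is enforced:
#' features consumed by data-driven segmentation are excluded from testing
#' unless the config sets `test$allow_leakage`.
#'
#' @param input An [msi_experiment()] (with masks or with a segmentation
#'   stage configured), or `"simulation1"` / `"simulation2"` to generate a
#'   preset dataset first.
#' @param config Named list overriding the defaults (see
#'   `msidiff:::default_workflow_config()`), or a path to a JSON file with
#'   the same structure.
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @return List with the per-stage results: `experiment`, `masks`,
#'   `normalization`, `status`, `ledger`, `results`, `power`, `config`.
#' @export
run_workflow <- function(input, config = list(), out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- merge_config(default_workflow_config(), config)
  log <- list(started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              config = cfg,
              package_version = as.character(utils::packageVersion("msidiff")))

  if (is.character(input)) {
    preset <- match.arg(input, c("simulation1", "simulation2"))
    sim <- simulate_experiment(
      if (preset == "simulation1") sim1_config(seed = cfg$seed)
      else sim2_config(seed = cfg$seed))
    exp <- sim$experiment
    truth <- sim$truth
  } else {
    stopifnot(inherits(input, "msi_experiment"))
    exp <- input
    truth <- NULL
  }

  # -- normalize ------------------------------------------------------------
  norm_report <- NULL
  if (identical(cfg$normalize$method, "censored-median")) {
    nm <- censored_median_normalize(exp, censor_q = cfg$normalize$censor_q)
    exp <- nm$experiment; norm_report <- nm$report
  } else if (cfg$normalize$method %in% c("tic", "rms", "reference")) {
    nm <- global_normalize(exp, method = cfg$normalize$method,
                           ref_feature = cfg$normalize$ref_feature)
    exp <- nm$experiment; norm_report <- nm$report
  } else if (!identical(cfg$normalize$method, "none")) {
    stop("stage 'normalize': unknown method ", cfg$normalize$method)
  }

  # -- segment --------------------------------------------------------------
  masks <- exp$roi_masks
  if (identical(cfg$segment$method, "gmm")) {
    masks <- lapply(exp$runs, function(run) {
      seg <- univariate_spatial_gmm(run, feature = cfg$segment$marker,
                                    k = if (is.null(cfg$segment$k)) 2
                                        else cfg$segment$k,
                                    seed = cfg$seed)
      m <- seg$mask
      # highest-mean component is the ROI
      top <- paste0("comp", length(seg$means))
      m$labels <- ifelse(m$labels == top, "roi", "background")
      m
    })
    names(masks) <- names(exp$runs)
  } else if (identical(cfg$segment$method, "truth")) {
    if (is.null(masks)) stop("stage 'segment': no truth masks available")
  } else if (!identical(cfg$segment$method, "none")) {
    stop("stage 'segment': unknown method ", cfg$segment$method)
  }
  if (is.null(masks)) stop("stage 'segment': no masks to analyse with")

  # -- filter ---------------------------------------------------------------
  status <- feature_status_init(exp, masks)
  if (!isTRUE(cfg$test$allow_leakage)) status <- mark_consumed(status, masks)
  status <- nonspecific_filter(status, q = cfg$filter$nonspecific_q)
  status <- roi_sparsity_filter(exp, status, masks,
                                label = cfg$test$roi_label,
                                max_sparsity = cfg$filter$max_roi_sparsity)
  if (isTRUE(cfg$filter$cluster)) {
    status <- cluster_related_features(
      exp, status, masks, mass_tol_ppm = cfg$filter$mass_tol_ppm,
      min_similarity = cfg$filter$min_similarity)
    agg <- aggregate_clusters(exp, status)
    status <- agg$status
  }
  ledger <- status_ledger(status)

  # -- test -----------------------------------------------------------------
  keep_mz <- status$mz[status$retained]
  summ <- summarize_roi_means(exp, masks, label = cfg$test$roi_label)
  summ <- summ[summ$mz %in% keep_mz, , drop = FALSE]
  class(summ) <- c("roi_summary", "data.frame")
  fits <- fit_roi_model(summ, model_spec(cfg$test$model))
  hyps <- cfg$test$hypotheses
  if (length(unique(exp$design$tissue)) < 2) hyps <- setdiff(hyps, c("B", "C"))
  if (length(unique(exp$design$condition)) < 2) hyps <- setdiff(hyps, c("A", "C"))
  if (length(hyps) == 0L) stop("stage 'test': no estimable hypotheses")
  results <- test_features(
    fits, hypotheses = hyps,
    exclude_mz = features_consumed(masks),
    allow_leakage = isTRUE(cfg$test$allow_leakage))

  # -- power ----------------------------------------------------------------
  vc <- variance_component_summary(fits)
  pw_spec <- power_spec(alpha = 0.05, q = cfg$power$q, beta = cfg$power$beta,
                        m0_over_m1 = cfg$power$m0_over_m1,
                        var_subject = vc["var_subject"],
                        var_tech = vc["var_tech"])
  baseline <- stats::median(status$mean[status$retained])
  pw <- power_curve(pw_spec, cfg$power$delta_pct_grid, baseline = baseline)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(norm_report)) {
      write_results(norm_report, file.path(out_dir, "normalization.csv"))
    }
    write_results(status, file.path(out_dir, "feature_status.csv"))
    write_results(ledger, file.path(out_dir, "feature_ledger.csv"))
    write_results(results, file.path(out_dir, "contrast_results.csv"))
    write_results(pw, file.path(out_dir, "power_curve.csv"))
    for (id in names(masks)) {
      write_mask_csv(masks[[id]], exp$runs[[id]]$coords,
                     file.path(out_dir, paste0("mask_", id, ".csv")))
    }
    log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    log$ledger <- ledger
    jsonlite::write_json(log, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(experiment = exp, masks = masks, normalization = norm_report,
       status = status, ledger = ledger, results = results, power = pw,
       truth = truth, config = cfg)
}

mask_agreement <- function(labels, truth_labels) {
  # two-class agreement up to label permutation
  a <- mean((labels == labels[1]) == (truth_labels == "roi"))
  max(a, 1 - a)
}

#' Segmentation-bias study (double-dipping and selection bias)
#'
#' Generates donut-ROI data, segments every image with the true mask, a
#' univariate marker GMM, spatial k-means, and shrunken centroids, and
#' quantifies (a) mask agreement with the truth, (b) the overlap between the
#' top-N multivariate importance features and the N true ROI-defining
#' features, (c) sensitivity of between-condition t-tests on within-ROI
#' means for the truly differential features under each ROI definition, and
#' (d) the null p-value distribution of within-sample tests between the two
#' multivariate segments (the double-dipping demonstration).
#'
#' @param seed Master seed.
#' @param reps Replicate datasets to average over.
#' @param config A `sim_config`; the default is a desk-scale reduction of
#'   the donut preset (2 images per condition, 60 x 60, 600 features) sized
#'   for minutes-scale runs; pass `sim1_config(seed)` for the full preset.
#' @return List with per-method mask agreement, top-feature overlap counts,
#'   sensitivity/FPR, the estimated between-condition difference for the
#'   differential features (its attenuation under intensity-driven masks is
#'   the selection-bias signature), the mean differential p-value (average
#'   conservatism), and the within-sample null p-values.
#' @export
run_segmentation_bias_study <- function(seed = 1, reps = 1,
                                        config = sim1_config(
                                          seed, dims = c(60, 60),
                                          n_features = 600,
                                          n_per_condition = 2)) {
  stopifnot(reps >= 1)
  methods <- c("truth", "gmm", "kmeans", "ssc")
  agreement <- stats::setNames(rep(0, length(methods)), methods)
  n_rep_runs <- 0
  overlap <- list(kmeans = integer(0), ssc = integer(0))
  sens <- stats::setNames(numeric(length(methods)), methods)
  fpr <- stats::setNames(numeric(length(methods)), methods)
  est_diff <- stats::setNames(numeric(length(methods)), methods)
  mean_p_diff <- stats::setNames(numeric(length(methods)), methods)
  null_p_within <- numeric(0)

  for (rep_i in seq_len(reps)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, "bias", rep_i)
    sim <- simulate_experiment(cfg)
    exp <- sim$experiment
    roles <- sim$truth$features
    roi_def <- which(roles$role == "roi_defining")
    diff_f <- which(roles$role == "differential")
    null_f <- which(roles$role == "null")
    marker_mz <- roles$mz[roi_def[1]]
    n_top <- length(roi_def)

    masks_by_method <- list()
    for (run_id in names(exp$runs)) {
      run <- exp$runs[[run_id]]
      truth_m <- sim$truth$roi_masks[[run_id]]
      segs <- list(truth = NULL, gmm = NULL, kmeans = NULL, ssc = NULL)

      g <- univariate_spatial_gmm(run, marker_mz, k = 2, seed = cfg$seed)
      g_roi <- ifelse(g$mask$labels == "comp2", "roi", "background")
      km <- spatial_kmeans(run, k = 2, seed = cfg$seed)
      sc <- shrunken_centroids_segment(run, k = 2, shrinkage_s = 1,
                                       seed = cfg$seed)
      masks_by_method$truth[[run_id]] <- truth_m$labels
      masks_by_method$gmm[[run_id]] <- g_roi
      masks_by_method$kmeans[[run_id]] <- km$mask$labels
      masks_by_method$ssc[[run_id]] <- sc$mask$labels

      agreement["truth"] <- agreement["truth"] + 1
      agreement["gmm"] <- agreement["gmm"] +
        mask_agreement(g_roi, truth_m$labels)
      agreement["kmeans"] <- agreement["kmeans"] +
        mask_agreement(km$mask$labels, truth_m$labels)
      agreement["ssc"] <- agreement["ssc"] +
        mask_agreement(sc$mask$labels, truth_m$labels)
      n_rep_runs <- n_rep_runs + 1

      overlap$kmeans <- c(overlap$kmeans,
                          sum(order(-km$importance)[seq_len(n_top)] %in%
                                roi_def))
      overlap$ssc <- c(overlap$ssc,
                       sum(order(-sc$importance)[seq_len(n_top)] %in%
                             roi_def))

      # double-dipping: within-sample pixel t-tests between the two
      # multivariate segments, on null features
      seg_lab <- km$mask$labels
      if (length(unique(seg_lab)) == 2) {
        in1 <- seg_lab == "comp1"
        sub_null <- with_seed(derive_seed(cfg$seed, "nullsub", run_id),
                              sample(null_f, min(60, length(null_f))))
        pv <- vapply(sub_null, function(f) {
          stats::t.test(run$intensities[in1, f],
                        run$intensities[!in1, f])$p.value
        }, numeric(1))
        null_p_within <- c(null_p_within, pv)
      }
    }

    # between-condition tests of within-ROI run means under each mask
    cond <- exp$design$condition
    for (m in methods) {
      roi_means <- vapply(names(exp$runs), function(run_id) {
        lab <- masks_by_method[[m]][[run_id]]
        roi_lab <- if (m %in% c("truth", "gmm")) "roi" else {
          # pick the segment best matching the truth donut per run
          tr <- sim$truth$roi_masks[[run_id]]$labels == "roi"
          m1 <- mean(lab[tr] == "comp1")
          m0 <- mean(lab[!tr] == "comp1")
          if (m1 >= m0) "comp1" else "comp2"
        }
        sel <- lab == roi_lab
        if (!any(sel)) sel <- rep(TRUE, length(lab))
        colMeans(exp$runs[[run_id]]$intensities[sel, c(diff_f, null_f),
                                                drop = FALSE])
      }, numeric(length(diff_f) + length(null_f)))
      tt <- apply(roi_means, 1, function(v) {
        ht <- stats::t.test(v[cond == "A"], v[cond == "B"],
                            var.equal = TRUE)
        c(p = ht$p.value, est = unname(diff(rev(ht$estimate))))
      })
      pvals <- tt["p", ]
      nd <- length(diff_f)
      sens[m] <- sens[m] + mean(pvals[seq_len(nd)] < 0.05)
      fpr[m] <- fpr[m] + mean(pvals[-seq_len(nd)] < 0.05)
      est_diff[m] <- est_diff[m] + mean(tt["est", seq_len(nd)])
      mean_p_diff[m] <- mean_p_diff[m] + mean(pvals[seq_len(nd)])
    }
  }

  list(mask_agreement = agreement / n_rep_runs,
       top_feature_overlap = overlap,
       sensitivity = sens / reps,
       fpr = fpr / reps,
       estimated_condition_difference = est_diff / reps,
       mean_p_differential = mean_p_diff / reps,
       null_p_within_sample = null_p_within,
       reps = reps, seed = seed)
}

#' Variance-structure (pseudoreplication) study
#'
#' Generates the paired-design dataset under both variance regimes (4:1 and
#' 1:4 technical:biological), fits the ROI-mean models M1/M2/M3 and their
#' pixel-as-replicate analogues, and tabulates true/false positive rates per
#' (model, hypothesis, regime) at unadjusted P < 0.05 (no multiplicity
#' correction, by design).
#'
#' @param seed Master seed.
#' @param reps Replicate datasets per regime.
#' @param dims,n_features Scale knobs for the generator (defaults are a
#'   desk-scale reduction; use `c(100, 100)` and 300 for the full preset).
#' @return Data frame `(regime, model, unit, hypothesis, tpr, fpr)`.
#' @export
run_variance_structure_study <- function(seed = 1, reps = 1,
                                         dims = c(40, 40),
                                         n_features = 300) {
  stopifnot(reps >= 1)
  rows <- list()
  for (regime in c("technical", "biological")) {
    acc <- list()
    for (rep_i in seq_len(reps)) {
      cfg <- sim2_config(seed = derive_seed(seed, regime, rep_i),
                         regime = regime, dims = dims,
                         n_features = n_features)
      sim <- simulate_experiment(cfg)
      exp <- sim$experiment
      roles <- sim$truth$features
      is_null <- roles$role == "null"
      summ <- summarize_roi_means(exp)

      settings <- list(
        list(model = "M1", unit = "roi_mean", hyp = "A"),
        list(model = "M2", unit = "roi_mean", hyp = "B"),
        list(model = "M3", unit = "roi_mean", hyp = "A"),
        list(model = "M3", unit = "roi_mean", hyp = "B"),
        list(model = "M1", unit = "pixel", hyp = "A"),
        list(model = "M2", unit = "pixel", hyp = "B"),
        list(model = "M3", unit = "pixel", hyp = "A"),
        list(model = "M3", unit = "pixel", hyp = "B"))
      for (s in settings) {
        fits <- if (s$unit == "roi_mean") {
          fit_roi_model(summ, model_spec(s$model))
        } else {
          fit_pixel_model(exp, spec = model_spec(s$model, unit = "pixel"))
        }
        p <- vapply(fits, function(f) contrast_test(f, s$hyp)$p, numeric(1))
        key <- paste(s$model, s$unit, s$hyp)
        acc[[key]] <- rbind(acc[[key]],
                            c(tpr = mean(p[!is_null] < 0.05),
                              fpr = mean(p[is_null] < 0.05)))
      }
    }
    for (key in names(acc)) {
      parts <- strsplit(key, " ")[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        regime = regime, model = parts[1], unit = parts[2],
        hypothesis = parts[3],
        tpr = mean(acc[[key]][, "tpr"]), fpr = mean(acc[[key]][, "fpr"]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
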