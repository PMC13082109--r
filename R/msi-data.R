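#' Construct a single MSI run
#'
#' An `msi_run` holds one sample's peak-picked mass spectrometry image: a set
#' of pixel coordinates, a shared m/z axis, and a pixel-by-feature intensity
#' matrix. Absent peaks are stored as zero (the sparse-fill convention used by
#' peak-picked MSI containers), so zeros are the only missing-value
#' representation.
#'
#' @param run_id Character scalar identifying the run (one tissue section).
#' @param coords Integer matrix with columns `x`, `y`: 0-based grid positions,
#'   one row per pixel. Grids may be ragged (tissue outlines); coordinates
#'   must be unique within the run.
#' @param mz Numeric vector of feature m/z values (Da), strictly increasing.
#' @param intensities Numeric matrix, `n_pixels x n_features`, non-negative.
#' @return An object of class `msi_run`.
#' @export
msi_run <- function(run_id, coords, mz, intensities) {
  stopifnot(is.character(run_id), length(run_id) == 1L)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coords must have two columns (x, y)")
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("x", "y")
  if (anyDuplicated(paste(coords[, 1], coords[, 2]))) {
    stop("duplicate pixel coordinates in run ", run_id)
  }
  mz <- as.numeric(mz)
  if (is.unsorted(mz, strictly = TRUE)) stop("mz axis must be strictly increasing")
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != nrow(coords) || ncol(intensities) != length(mz)) {
    stop("intensities must be n_pixels x n_features")
  }
  if (any(intensities < 0)) stop("intensities must be non-negative")
  structure(list(run_id = run_id, coords = coords, mz = mz,
                 intensities = intensities),
            class = "msi_run")
}

#' @export
print.msi_run <- function(x, ...) {
  cat(sprintf("<msi_run '%s'> %d pixels, %d features, m/z %.4f..%.4f\n",
              x$run_id, nrow(x$coords), length(x$mz),
              min(x$mz), max(x$mz)))
  invisible(x)
}

n_pixels <- function(run) nrow(run$coords)

#' Construct a multi-run MSI experiment
#'
#' Bundles runs sharing one m/z axis with the experimental design: one record
#' per run giving the subject, condition and tissue. Subjects index biological
#' replicates (`i = 1..I` per condition), conditions and tissues the crossed
#' fixed factors (`j = 1..J`, `k = 1..K`).
#'
#' @param runs List of [msi_run()] objects with identical `mz` vectors.
#' @param design Data frame with columns `run_id`, `subject`, `condition`,
#'   `tissue`; one row per run.
#' @param roi_masks Optional named list (by `run_id`) of [roi_mask()] objects.
#' @return An object of class `msi_experiment`.
#' @export
msi_experiment <- function(runs, design, roi_masks = NULL) {
  stopifnot(is.list(runs), length(runs) >= 1L)
  ids <- vapply(runs, function(r) r$run_id, character(1))
  names(runs) <- ids
  design <- as.data.frame(design)
  need <- c("run_id", "subject", "condition", "tissue")
  if (!all(need %in% names(design))) {
    stop("design must have columns ", paste(need, collapse = ", "))
  }
  if (!setequal(design$run_id, ids) || nrow(design) != length(ids)) {
    stop("design must have exactly one row per run")
  }
  design <- design[match(ids, design$run_id), , drop = FALSE]
  rownames(design) <- NULL
  mz0 <- runs[[1]]$mz
  for (r in runs) {
    if (length(r$mz) != length(mz0) || any(r$mz != mz0)) {
      stop("all runs must share an identical mz axis (see combine_runs)")
    }
  }
  if (!is.null(roi_masks)) check_masks(roi_masks, runs)
  structure(list(runs = runs, design = design, roi_masks = roi_masks),
            class = "msi_experiment")
}

#' @export
print.msi_experiment <- function(x, ...) {
  cat(sprintf("<msi_experiment> %d runs, %d features\n",
              length(x$runs), length(x$runs[[1]]$mz)))
  print(x$design)
  invisible(x)
}

check_masks <- function(masks, runs) {
  for (id in names(masks)) {
    if (!id %in% names(runs)) stop("mask for unknown run ", id)
    if (length(masks[[id]]$labels) != n_pixels(runs[[id]])) {
      stop("mask length does not match pixel count for run ", id)
    }
  }
  invisible(TRUE)
}

#' Construct a per-run ROI label mask
#'
#' One categorical label per pixel, plus provenance: how the mask was made
#' (`source`) and, for data-driven masks, which m/z features were consumed to
#' build it. The provenance is what lets downstream differential testing
#' enforce the anti-double-dipping rule (features used for segmentation are
#' excluded from testing).
#'
#' @param labels Character vector, one label per pixel (run pixel order).
#' @param source One of `"external"`, `"univariate"`, `"multivariate"`,
#'   `"simulated_truth"`.
#' @param features_consumed Numeric vector of m/z values used to construct the
#'   mask (empty for external or simulated-truth masks).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(labels, source = c("external", "univariate",
                                        "multivariate", "simulated_truth"),
                     features_consumed = numeric(0)) {
  source <- match.arg(source)
  labels <- as.character(labels)
  if (anyNA(labels)) stop("mask labels must not be NA")
  if (source %in% c("univariate", "multivariate") &&
      length(features_consumed) == 0L) {
    stop("data-driven masks must record the features consumed")
  }
  structure(list(labels = labels, source = source,
                 features_consumed = as.numeric(features_consumed)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<roi_mask source=%s> %d pixels: %s\n", x$source,
              length(x$labels),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Union of features consumed by a set of masks
#'
#' @param masks Named list of [roi_mask()] objects.
#' @return Numeric vector of m/z values (possibly empty).
#' @export
features_consumed <- function(masks) {
  sort(unique(unlist(lapply(masks, function(m) m$features_consumed))))
}
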