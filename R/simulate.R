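# Simulators of peak-picked multi-sample MSI experiments with ground truth.
#
# Pixel intensities are generated as
#   Y[p, f] = baseline_f + effect_f(condition, tissue, ROI(p))
#             + b[subject, f] + t[run, f] + pixel_noise_sd * field[p, f]
# where b ~ N(0, var_subject) is the biological (between-subject) intercept
# shared by all runs of a subject, t ~ N(0, var_tech) is the run-level
# technical intercept (the residual variance the downstream ROI-mean model
# sees), and `field` is a spatially autocorrelated, empirically standardized
# Gaussian field (Gaussian-kernel-smoothed white noise). Intensities are
# clamped at zero; baselines default high enough that clamping is rare.

# Evaluate f with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic stream seeds: mix the master seed with a stream tag so each
# (run, feature) / (subject) / (run) stream is reproducible independently of
# iteration order. Kept below 2^31 for R's 32-bit integer seeds.
derive_seed <- function(master, ...) {
  h <- as.numeric(master) %% 2147483647
  for (k in c(...)) {
    kv <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k))) else as.numeric(k)
    h <- (h * 48271 + kv * 8121 + 1) %% 2147483647
  }
  as.integer(h)
}

#' Donut-shaped ground-truth ROI mask
#'
#' Labels pixels `roi` when their Euclidean distance from the centre lies in
#' `[r_inner, r_outer)`, else `background`. The default radii on a
#' `100 x 100` grid cover about one-third of the image area, matching the
#' simulated ROI geometry used throughout the validation studies.
#'
#' @param dims `c(W, H)` grid dimensions in pixels.
#' @param center Donut centre `c(x, y)` in 0-based pixel units; defaults to
#'   the grid centre.
#' @param r_inner,r_outer Inner/outer radii in pixels, `0 <= r_inner <
#'   r_outer`. Defaults scale with the grid: `0.20 * W` and `0.38 * W`.
#' @return An [roi_mask()] with `source = "simulated_truth"`; pixel order is
#'   column-major (y fastest), the order used by [simulate_experiment()].
#' @export
make_donut_roi <- function(dims, center = (dims - 1) / 2,
                           r_inner = 0.20 * dims[1], r_outer = 0.38 * dims[1]) {
  W <- dims[1]; H <- dims[2]
  if (r_outer <= r_inner || r_inner < 0) {
    stop("need 0 <= r_inner < r_outer")
  }
  coords <- grid_coords(W, H)
  d <- sqrt((coords[, 1] - center[1])^2 + (coords[, 2] - center[2])^2)
  labels <- ifelse(d >= r_inner & d < r_outer, "roi", "background")
  roi_mask(labels, source = "simulated_truth")
}

grid_coords <- function(W, H) {
  cbind(x = rep(0:(W - 1), each = H), y = rep.int(0:(H - 1), W))
}

#' Spatially autocorrelated Gaussian random field
#'
#' White noise smoothed with a Gaussian kernel of the given scale (truncated
#' at 3 scales, boundary-renormalized), then empirically re-standardized to
#' zero mean and unit variance. `scale = 0` yields independent Normal noise.
#'
#' @param dims `c(W, H)` in pixels.
#' @param scale Correlation length in pixels (>= 0).
#' @param seed Integer seed; the same seed gives an identical field.
#' @return An `H x W` numeric matrix.
#' @export
gaussian_random_field <- function(dims, scale, seed) {
  if (scale < 0) stop("scale must be >= 0")
  W <- dims[1]; H <- dims[2]
  noise <- with_seed(seed, stats::rnorm(H * W))
  f <- smooth_fields(matrix(noise, ncol = 1), H, W, scale)[, 1]
  f <- (f - mean(f)) / stats::sd(f)
  matrix(f, H, W)
}

#' Simulation configuration
#'
#' Collects everything [simulate_experiment()] needs: grid and design,
#' per-feature baselines, an additive effect map, variance components and the
#' spatial correlation scale. Use [sim1_config()] / [sim2_config()] for the
#' two standard presets.
#'
#' @param design Data frame with columns `run_id`, `subject`, `condition`,
#'   `tissue` (one row per run).
#' @param dims `c(W, H)` grid dimensions.
#' @param n_features Number of spectral features.
#' @param baseline Baseline mean intensity (scalar or per-feature vector).
#' @param effects List of effect entries, each
#'   `list(features =, shift =, condition = NA, tissue = NA, roi_only = FALSE)`:
#'   `shift` is added to the listed features for runs matching `condition` /
#'   `tissue` (NA matches every run), inside the ROI only when `roi_only`.
#' @param var_subject Between-subject variance of the per-(subject, feature)
#'   random intercept (intensity^2).
#' @param var_tech Run-level technical variance of the per-(run, feature)
#'   intercept (intensity^2): this is the residual variance sigma^2 that the
#'   downstream ROI-mean model estimates.
#' @param pixel_noise_sd SD of the within-image (pixel) noise field.
#' @param autocorr_scale Spatial correlation length of the pixel noise, px.
#' @param roi Either `NULL` (the whole image is the ROI) or
#'   `list(type = "donut", center =, r_inner =, r_outer =)`.
#' @param dropout Uniform probability of zeroing any (pixel, feature) value
#'   (sparsity knob; default 0, i.e. no missingness mechanism).
#' @param seed Master seed; every random stream is derived from it.
#' @param mz Optional m/z axis (defaults to an evenly spaced synthetic axis).
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(design, dims = c(100, 100), n_features = 300,
                              baseline = 100, effects = list(),
                              var_subject = 0, var_tech = 0,
                              pixel_noise_sd = 0, autocorr_scale = 2,
                              roi = NULL, dropout = 0, seed = 1,
                              mz = NULL) {
  design <- as.data.frame(design)
  stopifnot(all(c("run_id", "subject", "condition", "tissue") %in% names(design)))
  if (any(dims <= 0)) stop("dims must be positive")
  if (var_subject < 0 || var_tech < 0 || pixel_noise_sd < 0) {
    stop("variances must be >= 0")
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  baseline <- rep_len(baseline, n_features)
  effects <- lapply(effects, function(e) {
    if (is.null(e$condition)) e$condition <- NA
    if (is.null(e$tissue)) e$tissue <- NA
    if (is.null(e$roi_only)) e$roi_only <- FALSE
    if (is.null(e$features) || is.null(e$shift)) {
      stop("each effect entry needs 'features' and 'shift'")
    }
    if (any(e$features < 1 | e$features > n_features)) {
      stop("effect entry references features outside 1..n_features")
    }
    e
  })
  if (is.null(mz)) mz <- seq(600, by = 1.5, length.out = n_features)
  structure(list(design = design, dims = dims, n_features = n_features,
                 baseline = baseline, effects = effects,
                 var_subject = var_subject, var_tech = var_tech,
                 pixel_noise_sd = pixel_noise_sd,
                 autocorr_scale = autocorr_scale, roi = roi,
                 dropout = dropout, seed = as.integer(seed), mz = mz),
            class = "sim_config")
}

#' Swap the biological and technical variance regime
#'
#' Inverts the ratio of the between-subject and technical variance components
#' while preserving their sum, so the total variation stays the same.
#'
#' @param config A `sim_config`.
#' @return The config with `var_subject` and `var_tech` exchanged.
#' @export
swap_variance_regime <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  total <- config$var_subject + config$var_tech
  if (total <= 0) stop("total variance must be positive to swap regimes")
  tmp <- config$var_subject
  config$var_subject <- config$var_tech
  config$var_tech <- tmp
  config
}

#' Preset: donut-ROI segmentation-bias simulation
#'
#' Eight single-tissue images in two conditions sharing a donut ROI covering
#' about one-third of each image. Features 1..`n_roi_def` are shifted +40
#' inside the ROI in every image (ROI-defining); the last `n_diff` features
#' are shifted +30 inside the ROI in condition-A images only (differential);
#' the middle block is null. Defaults follow the stated design: 8 runs of
#' 100 x 100 pixels, 3000 features split 100 / 2400 / 500.
#'
#' @param seed Master seed.
#' @param dims,n_features,n_per_condition,n_roi_def,n_diff Scale knobs; the
#'   defaults are the preset. Scaled-down values are for fast property tests.
#' @return A `sim_config`.
#' @export
sim1_config <- function(seed = 1, dims = c(100, 100), n_features = 3000,
                        n_per_condition = 4,
                        n_roi_def = round(n_features / 30),
                        n_diff = round(n_features / 6)) {
  n_runs <- 2 * n_per_condition
  design <- data.frame(
    run_id = sprintf("img%02d", seq_len(n_runs)),
    subject = sprintf("subj%02d", seq_len(n_runs)),
    condition = rep(c("A", "B"), each = n_per_condition),
    tissue = "T1")
  effects <- list(
    list(features = seq_len(n_roi_def), shift = 40,
         condition = NA, tissue = NA, roi_only = TRUE),
    list(features = seq.int(n_features - n_diff + 1, n_features), shift = 30,
         condition = "A", tissue = NA, roi_only = TRUE))
  simulation_config(
    design = design, dims = dims, n_features = n_features, baseline = 100,
    effects = effects, var_subject = 0, var_tech = 4, pixel_noise_sd = 10,
    autocorr_scale = 2,
    roi = list(type = "donut", center = (dims - 1) / 2,
               r_inner = 0.20 * dims[1], r_outer = 0.38 * dims[1]),
    seed = seed)
}

#' Preset: variance-structure (pseudoreplication) simulation
#'
#' Sixteen images from a 2 conditions x 2 tissues x 4 subjects-per-condition
#' paired design (each subject contributes both tissues). Half of the
#' features are null; the other half carry additive condition (+2 for the
#' first condition) and tissue (+2 for the first tissue) effects. The
#' `"technical"` regime uses a 4:1 technical:biological variance ratio
#' (`var_tech = 4`, `var_subject = 1`); `"biological"` reverses it with the
#' total preserved.
#'
#' @param seed Master seed.
#' @param regime `"technical"` (4:1) or `"biological"` (1:4).
#' @param dims,n_features,n_subjects_per_condition Scale knobs; defaults are
#'   the preset (100 x 100, 300 features, 4 subjects per condition).
#' @return A `sim_config`.
#' @export
sim2_config <- function(seed = 1, regime = c("technical", "biological"),
                        dims = c(100, 100), n_features = 300,
                        n_subjects_per_condition = 4) {
  regime <- match.arg(regime)
  subj <- sprintf("subj%02d", seq_len(2 * n_subjects_per_condition))
  cond <- rep(c("A", "B"), each = n_subjects_per_condition)
  design <- data.frame(
    run_id = paste0(rep(subj, each = 2), "-", c("medial", "lateral")),
    subject = rep(subj, each = 2),
    condition = rep(cond, each = 2),
    tissue = c("medial", "lateral"))
  n_diff <- floor(n_features / 2)
  diff_features <- seq.int(n_features - n_diff + 1, n_features)
  effects <- list(
    list(features = diff_features, shift = 2, condition = "A", tissue = NA,
         roi_only = FALSE),
    list(features = diff_features, shift = 2, condition = NA,
         tissue = "medial", roi_only = FALSE))
  cfg <- simulation_config(
    design = design, dims = dims, n_features = n_features, baseline = 100,
    effects = effects, var_subject = 1, var_tech = 4, pixel_noise_sd = 5,
    autocorr_scale = 2, roi = NULL, seed = seed)
  if (regime == "biological") cfg <- swap_variance_regime(cfg)
  cfg
}

sim_roi_mask <- function(config) {
  if (is.null(config$roi)) {
    roi_mask(rep("roi", prod(config$dims)), source = "simulated_truth")
  } else if (identical(config$roi$type, "donut")) {
    make_donut_roi(config$dims, center = config$roi$center,
                   r_inner = config$roi$r_inner, r_outer = config$roi$r_outer)
  } else {
    stop("unknown roi type: ", config$roi$type)
  }
}

#' Simulate a peak-picked MSI experiment with ground truth
#'
#' Generates the experiment described by a `sim_config` (see the generator
#' model in the package vignette) together with its ground truth: the true
#' ROI mask of every run and per-feature roles (`roi_defining`,
#' `differential`, `null`) with true effect sizes.
#'
#' All randomness is drawn from streams derived from the master seed, one per
#' subject (biological intercepts), per run (technical intercepts, dropout)
#' and per (run, feature) (pixel noise), so output is reproducible and
#' independent of iteration order.
#'
#' @param config A `sim_config` from [simulation_config()] or a preset.
#' @return A list with elements `experiment` (an [msi_experiment()]) and
#'   `truth` (list of `roi_masks`, `features` data frame, `config`).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  design <- config$design
  W <- config$dims[1]; H <- config$dims[2]
  np <- W * H
  F <- config$n_features
  coords <- grid_coords(W, H)
  mask <- sim_roi_mask(config)
  in_roi <- mask$labels == "roi"

  subjects <- unique(design$subject)
  sd_subj <- sqrt(config$var_subject)
  sd_run <- sqrt(config$var_tech)
  b_subj <- matrix(0, length(subjects), F,
                   dimnames = list(subjects, NULL))
  for (s in seq_along(subjects)) {
    if (sd_subj > 0) {
      b_subj[s, ] <- with_seed(derive_seed(config$seed, "subject", s),
                               stats::rnorm(F, 0, sd_subj))
    }
  }

  runs <- vector("list", nrow(design))
  roi_masks <- list()
  chunk_size <- 512L                  # features per smoothing/assembly chunk
  for (r in seq_len(nrow(design))) {
    drow <- design[r, ]
    run_shift <- config$baseline + b_subj[drow$subject, ]
    if (sd_run > 0) {
      run_shift <- run_shift + with_seed(derive_seed(config$seed, "run", r),
                                         stats::rnorm(F, 0, sd_run))
    }
    mat <- matrix(0, np, F)
    for (start in seq(1L, F, by = chunk_size)) {
      cols <- start:min(start + chunk_size - 1L, F)
      if (config$pixel_noise_sd > 0) {
        chunk <- matrix(0, np, length(cols))
        for (ci in seq_along(cols)) {
          chunk[, ci] <- with_seed(
            derive_seed(config$seed, "pixel", r, cols[ci]),
            stats::rnorm(np))
        }
        chunk <- smooth_fields(chunk, H, W, config$autocorr_scale)
        cm <- colMeans(chunk)
        csd <- sqrt((colSums(chunk^2) - np * cm^2) / (np - 1))
        chunk <- sweep(sweep(chunk, 2, cm, "-"), 2,
                       csd / config$pixel_noise_sd, "/")
      } else {
        chunk <- matrix(0, np, length(cols))
      }
      chunk <- sweep(chunk, 2, run_shift[cols], "+")
      for (e in config$effects) {
        if (!is.na(e$condition) && e$condition != drow$condition) next
        if (!is.na(e$tissue) && e$tissue != drow$tissue) next
        hit <- which(cols %in% e$features)
        if (length(hit) == 0L) next
        if (isTRUE(e$roi_only)) {
          chunk[in_roi, hit] <- chunk[in_roi, hit] + e$shift
        } else {
          chunk[, hit] <- chunk[, hit] + e$shift
        }
      }
      chunk[chunk < 0] <- 0
      mat[, cols] <- chunk
    }
    if (config$dropout > 0) {
      drop <- with_seed(derive_seed(config$seed, "dropout", r),
                        stats::runif(np * F) < config$dropout)
      mat[drop] <- 0
    }
    runs[[r]] <- msi_run(drow$run_id, coords, config$mz, mat)
    roi_masks[[drow$run_id]] <- mask
    rm(mat)
  }

  truth <- list(
    roi_masks = roi_masks,
    features = feature_roles(config),
    config = config)
  list(experiment = msi_experiment(runs, design, roi_masks = roi_masks),
       truth = truth)
}

# Classify features by the effect entries: ROI-only shifts applying to every
# run mark ROI-defining features; condition- or tissue-specific shifts mark
# differential features; the rest are null.
feature_roles <- function(config) {
  F <- config$n_features
  role <- rep("null", F)
  effect <- numeric(F)
  for (e in config$effects) {
    cond_specific <- (!is.na(e$condition)) ||
      (!is.null(e$tissue) && !is.na(e$tissue))
    role[e$features] <- ifelse(cond_specific, "differential",
                               ifelse(isTRUE(e$roi_only), "roi_defining",
                                      role[e$features]))
    effect[e$features] <- effect[e$features] + e$shift
  }
  data.frame(feature = seq_len(F), mz = config$mz, role = role,
             true_effect = effect)
}
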