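# ROI construction. The recommended route for differential analysis is
# univariate segmentation of a small number of marker features (subsequently
# excluded from testing); the multivariate methods (spatial k-means and a
# shrunken-centroids variant) are provided chiefly to demonstrate the
# double-dipping and selection-bias failure modes they induce.

# Spatially regularized univariate Gaussian-mixture EM: after each E-step the
# per-pixel posteriors of each iteration are Gaussian-kernel smoothed and
# serve as pixelwise mixing priors for the next E-step (the spatially
# variant finite-mixture formulation; "sDGMM-lite", no Dirichlet adaptive
# weighting). Component moments are computed from the un-diffused
# posteriors, so smoothing regularizes the label field without inflating
# the component variances. smooth_scale = 0 keeps global mixing
# proportions and reduces to plain EM.
spatial_gmm_fit <- function(y, coords, k, smooth_scale, max_iter, tol, seed) {
  n <- length(y)
  if (length(unique(y)) < k) {
    stop("degenerate input: fewer distinct intensity values than components")
  }
  probs <- if (k == 1) 0.5 else 0.05 + 0.9 * (seq_len(k) - 1) / (k - 1)
  qs <- stats::quantile(y, probs = probs, names = FALSE)
  mu <- with_seed(seed, qs + stats::rnorm(k, 0, stats::sd(y) * 1e-3))
  v <- rep(stats::var(y), k)
  prior <- matrix(1 / k, n, k)        # pixelwise mixing priors
  pi_k <- rep(1 / k, k)
  ll_old <- -Inf
  converged <- FALSE
  resp <- NULL
  for (it in seq_len(max_iter)) {
    lik <- vapply(seq_len(k), function(j) {
      stats::dnorm(y, mu[j], sqrt(v[j]))
    }, numeric(n))
    dens <- if (smooth_scale > 0) prior * lik else
      lik * rep(pi_k, each = n)
    rs <- rowSums(dens)
    rs[rs == 0] <- .Machine$double.xmin
    ll <- sum(log(rs))
    resp <- dens / rs
    nk <- colSums(resp)
    nk[nk == 0] <- 1e-12
    mu <- colSums(resp * y) / nk
    v <- pmax(colSums(resp * (y - rep(mu, each = n))^2) / nk, 1e-12)
    pi_k <- nk / n
    if (smooth_scale > 0) {
      prior <- smooth_pixel_matrix(resp, coords, smooth_scale)
      prior <- prior / rowSums(prior)
    }
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  assign <- max.col(resp, ties.method = "first")
  list(assignment = assign, posteriors = resp, means = mu, vars = v,
       props = pi_k, loglik = ll_old, converged = converged)
}

segmentation_result <- function(mask, posteriors, importance = NULL,
                                features_consumed, details = list()) {
  structure(c(list(mask = mask, posteriors = posteriors,
                   importance = importance,
                   features_consumed = features_consumed), details),
            class = "segmentation_result")
}

#' Univariate spatial Gaussian-mixture segmentation of one marker feature
#'
#' Fits a k-component Gaussian mixture to one feature's pixel intensities by
#' EM with spatial regularization: after each iteration the per-pixel
#' posteriors are smoothed with a Gaussian kernel (truncated at 3 scales,
#' boundary-renormalized) and act as pixelwise mixing priors for the next
#' E-step, so neighbouring pixels favour the same component. Pixels are
#' assigned their maximum-posterior component, ties broken toward the lower
#' component index. Components are labelled `comp1..compk` in order of
#' increasing mean intensity. `smooth_scale = 0` reduces to plain EM.
#'
#' @param run An [msi_run()].
#' @param feature Marker m/z (must be on the axis).
#' @param k Number of components (>= 2).
#' @param smooth_scale Spatial smoothing scale in pixels (0 = plain EM).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param seed Seed for the (slight) random jitter of the quantile-based
#'   initialization.
#' @return A `segmentation_result`; its mask has `source = "univariate"` and
#'   records the marker as consumed.
#' @export
univariate_spatial_gmm <- function(run, feature, k = 2, smooth_scale = 2,
                                   max_iter = 100, tol = 1e-8, seed = 1) {
  stopifnot(inherits(run, "msi_run"), k >= 2)
  col <- feature_index(run$mz, feature)
  y <- run$intensities[, col]
  fit <- spatial_gmm_fit(y, run$coords, k, smooth_scale, max_iter, tol, seed)
  ord <- order(fit$means)                     # comp1 = lowest-mean component
  rank_of <- match(seq_len(k), ord)
  labels <- paste0("comp", rank_of[fit$assignment])
  mask <- roi_mask(labels, source = "univariate",
                   features_consumed = run$mz[col])
  segmentation_result(mask, fit$posteriors,
                      features_consumed = run$mz[col],
                      details = list(means = fit$means[ord],
                                     vars = fit$vars[ord],
                                     props = fit$props[ord],
                                     converged = fit$converged,
                                     loglik = fit$loglik))
}

#' Nested univariate segmentation
#'
#' Applies univariate spatial GMM segmentation in stages, each stage
#' restricted to the pixels left unlabelled by earlier stages (e.g. cartilage
#' first, then bone among the remaining pixels, the rest background). When a
#' stage lists several features, their pixel-wise mean image is segmented.
#' In every stage the highest-mean component receives the stage's target
#' label. All marker m/z used across stages are recorded as consumed.
#'
#' @param run An [msi_run()].
#' @param stage_specs List of stages, each
#'   `list(features =, k =, target_label =)`.
#' @param smooth_scale,max_iter,tol,seed Passed to the per-stage GMM.
#' @param residual_label Label given to pixels left after the last stage.
#' @return An [roi_mask()] with `source = "univariate"`.
#' @export
nested_segmentation <- function(run, stage_specs, smooth_scale = 2,
                                max_iter = 100, tol = 1e-8, seed = 1,
                                residual_label = "background") {
  stopifnot(inherits(run, "msi_run"), length(stage_specs) >= 1)
  n <- n_pixels(run)
  labels <- rep(NA_character_, n)
  consumed <- numeric(0)
  for (s in seq_along(stage_specs)) {
    sp <- stage_specs[[s]]
    active <- which(is.na(labels))
    if (length(active) == 0L) {
      stop("stage ", s, " ('", sp$target_label, "') has no remaining pixels")
    }
    cols <- vapply(sp$features, function(f) feature_index(run$mz, f),
                   integer(1))
    consumed <- c(consumed, run$mz[cols])
    y <- rowMeans(run$intensities[active, cols, drop = FALSE])
    k <- if (is.null(sp$k)) 2 else sp$k
    fit <- spatial_gmm_fit(y, run$coords[active, , drop = FALSE], k,
                           smooth_scale, max_iter, tol,
                           seed = derive_seed(seed, "stage", s))
    target_comp <- which.max(fit$means)
    labels[active[fit$assignment == target_comp]] <- sp$target_label
  }
  labels[is.na(labels)] <- residual_label
  roi_mask(labels, source = "univariate",
           features_consumed = sort(unique(consumed)))
}

#' Rank features by colocalization with a reference image
#'
#' Computes the spatial similarity (Pearson correlation or cosine) of every
#' feature's image with a reference feature's image, over non-background
#' pixels pooled across all runs, and ranks features by descending
#' similarity. The reference itself is excluded from the ranking.
#'
#' @param exp An [msi_experiment()].
#' @param ref_feature Reference m/z.
#' @param metric `"pearson"` or `"cosine"`.
#' @param masks Optional masks; pixels labelled `background` are excluded.
#' @return Data frame `(mz, similarity, rank)` sorted by rank.
#' @export
colocalization_rank <- function(exp, ref_feature,
                                metric = c("pearson", "cosine"),
                                masks = exp$roi_masks) {
  stopifnot(inherits(exp, "msi_experiment"))
  metric <- match.arg(metric)
  mz <- exp$runs[[1]]$mz
  ref_col <- feature_index(mz, ref_feature)
  mats <- lapply(exp$runs, function(run) {
    ints <- run$intensities
    if (!is.null(masks) && !is.null(masks[[run$run_id]])) {
      ints <- ints[masks[[run$run_id]]$labels != "background", ,
                   drop = FALSE]
    }
    ints
  })
  X <- do.call(rbind, mats)
  ref <- X[, ref_col]
  if (stats::sd(ref) == 0) stop("reference feature has zero variance")
  sim <- if (metric == "pearson") {
    suppressWarnings(as.numeric(stats::cor(X, ref)))
  } else {
    as.numeric(crossprod(X, ref)) /
      (sqrt(colSums(X^2)) * sqrt(sum(ref^2)))
  }
  sim[!is.finite(sim)] <- 0
  df <- data.frame(mz = mz, similarity = sim)[-ref_col, ]
  df <- df[order(-df$similarity), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

# Standardize feature columns and spatially smooth each feature image.
standardize_smooth <- function(run, smooth_scale) {
  X <- run$intensities
  cm <- colMeans(X)
  csd <- sqrt(pmax(colMeans(X^2) - cm^2, 0) * nrow(X) / (nrow(X) - 1))
  csd[csd == 0] <- 1
  X <- sweep(sweep(X, 2, cm, "-"), 2, csd, "/")
  if (smooth_scale > 0) X <- smooth_run_matrix(X, run$coords, smooth_scale)
  X
}

# Batched smoothing of every column of a pixel-by-feature matrix. Full
# rectangular grids use the fast gemm path; ragged grids fall back to
# per-column masked smoothing.
smooth_run_matrix <- function(X, coords, scale) {
  if (scale <= 0) return(X)
  x <- coords[, 1] - min(coords[, 1])
  y <- coords[, 2] - min(coords[, 2])
  W <- max(x) + 1L; H <- max(y) + 1L
  if (nrow(coords) == W * H) {
    idx <- y + 1L + H * x
    G <- matrix(0, W * H, ncol(X))
    G[idx, ] <- X
    G <- smooth_fields(G, H, W, scale)
    return(G[idx, , drop = FALSE])
  }
  apply(X, 2, smooth_pixel_values, coords = coords, scale = scale)
}

# k-means++-style farthest-point seeding under a fixed seed.
kmeanspp_centers <- function(X, k, seed) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- with_seed(seed, sample.int(n, 1))
  d2 <- rowSums((X - rep(X[centers[1], ], each = n))^2)
  for (j in seq_len(k - 1)) {
    centers[j + 1] <- which.max(d2)
    dn <- rowSums((X - rep(X[centers[j + 1], ], each = n))^2)
    d2 <- pmin(d2, dn)
  }
  X[centers, , drop = FALSE]
}

#' Spatial k-means segmentation
#'
#' k-means on per-pixel feature vectors after per-feature standardization and
#' Gaussian spatial smoothing of each feature image. A multivariate,
#' intensity-driven method: every feature is consumed, and the resulting
#' mask is therefore incompatible with downstream differential testing of
#' those features (the selection-bias demonstration).
#'
#' @param run An [msi_run()].
#' @param k Number of clusters (>= 2, <= number of pixels).
#' @param smooth_scale Spatial smoothing scale in pixels.
#' @param seed Seed for the farthest-point initialization.
#' @return A `segmentation_result` with per-feature importance scores
#'   (between-cluster variance / total variance); mask source
#'   `"multivariate"`.
#' @export
spatial_kmeans <- function(run, k = 2, smooth_scale = 2, seed = 1) {
  stopifnot(inherits(run, "msi_run"), k >= 2)
  if (k > n_pixels(run)) stop("k exceeds the number of pixels")
  X <- standardize_smooth(run, smooth_scale)
  centers <- kmeanspp_centers(X, k, seed)
  km <- suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 50))
  assign <- km$cluster
  # importance: between-cluster variance fraction per feature
  tot <- colSums(sweep(X, 2, colMeans(X))^2)
  within <- Reduce(`+`, lapply(seq_len(k), function(j) {
    sub <- X[assign == j, , drop = FALSE]
    if (nrow(sub) == 0) return(numeric(ncol(X)))
    colSums(sweep(sub, 2, colMeans(sub))^2)
  }))
  importance <- ifelse(tot > 0, 1 - within / tot, 0)
  post <- matrix(0, nrow(X), k)
  post[cbind(seq_len(nrow(X)), assign)] <- 1
  labels <- paste0("comp", assign)
  mask <- roi_mask(labels, source = "multivariate",
                   features_consumed = run$mz)
  segmentation_result(mask, post, importance = importance,
                      features_consumed = run$mz,
                      details = list(centers = km$centers,
                                     converged = km$iter < 50))
}

#' Spatially smoothed shrunken-centroids segmentation
#'
#' Iterative clustering in which class centroids are soft-thresholded toward
#' the global centroid by `shrinkage_s` (in pooled within-class SD units)
#' and pixels are reassigned by spatially smoothed nearest-shrunken-centroid
#' posteriors ("SSC-lite"). Per-feature importance is the largest absolute
#' shrunken centroid deviation; with `shrinkage_s` large enough all
#' deviations vanish and the result collapses to a single cluster (flagged
#' `degenerate`).
#'
#' @param run An [msi_run()].
#' @param k Number of classes (>= 2).
#' @param shrinkage_s Shrinkage threshold `s >= 0` (0 = no shrinkage).
#' @param smooth_scale Spatial smoothing of the class posteriors, pixels.
#' @param seed Seed for the k-means initialization.
#' @param max_iter Iteration cap.
#' @return A `segmentation_result` with importance scores and mask source
#'   `"multivariate"`.
#' @export
shrunken_centroids_segment <- function(run, k = 2, shrinkage_s = 1,
                                       smooth_scale = 2, seed = 1,
                                       max_iter = 20) {
  stopifnot(inherits(run, "msi_run"), k >= 2, shrinkage_s >= 0)
  X <- standardize_smooth(run, smooth_scale)
  n <- nrow(X); p <- ncol(X)
  km0 <- suppressWarnings(stats::kmeans(X, centers = kmeanspp_centers(X, k, seed),
                                        iter.max = 50))
  assign <- km0$cluster
  g <- colMeans(X)
  importance <- numeric(p)
  shrunk <- NULL
  for (it in seq_len(max_iter)) {
    nk <- tabulate(assign, nbins = k)
    if (any(nk == 0)) break
    cent <- rowsum(X, assign) / nk
    # pooled within-class SD per feature (+ median offset for stability)
    wss <- Reduce(`+`, lapply(seq_len(k), function(j) {
      sub <- X[assign == j, , drop = FALSE]
      colSums(sweep(sub, 2, cent[j, ])^2)
    }))
    s_j <- sqrt(wss / max(1, n - k))
    s0 <- stats::median(s_j)
    mk <- sqrt(pmax(1 / nk - 1 / n, 1e-12))
    d <- sweep(cent, 2, g) / outer(mk, s_j + s0)
    d_shr <- sign(d) * pmax(abs(d) - shrinkage_s, 0)
    shrunk <- sweep(d_shr * outer(mk, s_j + s0), 2, g, "+")
    importance <- apply(abs(d_shr), 2, max)
    if (all(importance == 0)) {
      return(segmentation_result(
        roi_mask(rep("comp1", n), source = "multivariate",
                 features_consumed = run$mz),
        matrix(1, n, 1), importance = importance,
        features_consumed = run$mz,
        details = list(degenerate = TRUE, shrunken_centroids = shrunk)))
    }
    scores <- -0.5 * outer_dist2_scaled(X, shrunk, s_j + s0)
    scores <- sweep(scores, 2, log(pmax(nk / n, 1e-12)), "+")
    post <- exp(scores - apply(scores, 1, max))
    post <- post / rowSums(post)
    if (smooth_scale > 0) {
      post <- smooth_run_matrix(post, run$coords, smooth_scale)
      post <- post / rowSums(post)
    }
    new_assign <- max.col(post, ties.method = "first")
    if (all(new_assign == assign)) { assign <- new_assign; break }
    assign <- new_assign
  }
  post <- matrix(0, n, k)
  post[cbind(seq_len(n), assign)] <- 1
  mask <- roi_mask(paste0("comp", assign), source = "multivariate",
                   features_consumed = run$mz)
  segmentation_result(mask, post, importance = importance,
                      features_consumed = run$mz,
                      details = list(degenerate = FALSE,
                                     shrunken_centroids = shrunk))
}

outer_dist2 <- function(X, C) {
  # n x k squared Euclidean distances
  xx <- rowSums(X^2)
  cc <- rowSums(C^2)
  outer(xx, cc, "+") - 2 * X %*% t(C)
}

outer_dist2_scaled <- function(X, C, s) {
  Xs <- sweep(X, 2, s, "/")
  Cs <- sweep(C, 2, s, "/")
  outer_dist2(Xs, Cs)
}
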