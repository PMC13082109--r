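# ROI segmentation: univariate spatial GMM, nesting, colocalization,
# multivariate methods, and the anti-leakage bookkeeping.

make_blob_run <- function(seed = 1, W = 30, H = 30, mu = c(0, 40), sd = 5) {
  set.seed(seed)
  coords <- grid_coords(W, H)
  right <- coords[, 1] >= W / 2
  y <- ifelse(right, mu[2], mu[1]) + stats::rnorm(W * H, 0, sd)
  list(run = msi_run("blob", coords, 700, cbind(pmax(y, 0))), truth = right)
}

test_that("spatial GMM separates well-separated blobs (>= 99% agreement)", {
  bl <- make_blob_run()
  seg <- univariate_spatial_gmm(bl$run, 700, k = 2, smooth_scale = 2)
  expect_gte(two_class_agreement(seg$mask$labels, bl$truth), 0.99)
  expect_identical(seg$mask$source, "univariate")
  expect_equal(seg$features_consumed, 700)
  # posteriors sum to 1 per pixel
  expect_equal(rowSums(seg$posteriors), rep(1, 900), tolerance = 1e-8)
})

test_that("constant image raises a degenerate-input error", {
  run <- toy_run(4, 4, matrix(5, 16, 1))
  expect_error(univariate_spatial_gmm(run, run$mz[1], k = 2), "degenerate")
})

test_that("smooth_scale = 0 reduces to plain EM (independent oracle)", {
  bl <- make_blob_run(seed = 8)
  seg <- univariate_spatial_gmm(bl$run, 700, k = 2, smooth_scale = 0,
                                tol = 1e-10, max_iter = 500)
  # independent plain-EM oracle on the same data
  y <- bl$run$intensities[, 1]
  mu <- stats::quantile(y, c(0.05, 0.95), names = FALSE)
  v <- rep(stats::var(y), 2); pk <- c(0.5, 0.5)
  for (i in 1:500) {
    d <- cbind(pk[1] * stats::dnorm(y, mu[1], sqrt(v[1])),
               pk[2] * stats::dnorm(y, mu[2], sqrt(v[2])))
    r <- d / rowSums(d)
    nk <- colSums(r)
    mu_new <- colSums(r * y) / nk
    v <- colSums(r * (y - rep(mu_new, each = length(y)))^2) / nk
    pk <- nk / length(y)
    if (max(abs(mu_new - mu)) < 1e-12) { mu <- mu_new; break }
    mu <- mu_new
  }
  expect_equal(sort(seg$means), sort(mu), tolerance = 1e-4)
})

test_that("nested segmentation: single stage, 3-class recovery, bookkeeping", {
  # 3-region truth on a 30x30 grid: ring marker (feature 1), background
  # marker (feature 2) high outside tissue, feature 3 uninformative
  set.seed(5)
  W <- H <- 30
  coords <- grid_coords(W, H)
  d <- sqrt((coords[, 1] - 14.5)^2 + (coords[, 2] - 14.5)^2)
  ring <- d >= 6 & d < 12
  outer <- d >= 12
  f1 <- ifelse(ring, 50, 5) + stats::rnorm(W * H, 0, 3)
  f2 <- ifelse(outer, 60, 8) + stats::rnorm(W * H, 0, 3)
  f3 <- stats::rnorm(W * H, 20, 3)
  run <- msi_run("nest", coords, c(800, 900, 1000),
                 pmax(cbind(f1, f2, f3), 0))
  # single stage is the univariate GMM
  one <- nested_segmentation(run, list(list(features = 800, k = 2,
                                            target_label = "ring")))
  seg <- univariate_spatial_gmm(run, 800, k = 2)
  expect_equal(one$labels == "ring", seg$mask$labels == "comp2")
  # two stages recover the 3-class truth
  mask <- nested_segmentation(run, list(
    list(features = 800, k = 2, target_label = "ring"),
    list(features = 900, k = 2, target_label = "outer")))
  truth <- ifelse(ring, "ring", ifelse(outer, "outer", "background"))
  expect_gte(mean(mask$labels == truth), 0.95)
  expect_equal(mask$features_consumed, c(800, 900))
})

test_that("colocalization ranking matches brute-force correlation", {
  set.seed(21)
  n <- 200
  ref <- stats::rexp(n, 1 / 10)
  X <- cbind(ref, ref * 3,                       # exact scalar multiple
             sapply(1:18, function(i) stats::rexp(n, 1 / 10)))
  run <- toy_run(20, 10, X)
  e <- toy_experiment(list(run))
  rk <- colocalization_rank(e, run$mz[1], metric = "cosine")
  expect_equal(rk$mz[1], run$mz[2])
  expect_equal(rk$similarity[1], 1, tolerance = 1e-12)
  # independent-noise features sit near zero under pearson
  rkp <- colocalization_rank(e, run$mz[1], metric = "pearson")
  expect_lt(max(abs(rkp$similarity[-1])), 0.35)
  # brute-force all-pairs oracle
  brute <- sapply(2:20, function(j) stats::cor(X[, 1], X[, j]))
  expect_equal(rkp$similarity[order(rkp$mz)], brute[order(run$mz[-1])],
               tolerance = 1e-12)
  # constant reference errors
  Xc <- X; Xc[, 1] <- 1
  ec <- toy_experiment(list(toy_run(20, 10, Xc)))
  expect_error(colocalization_rank(ec, run$mz[1]), "variance")
})

test_that("spatial k-means: degenerate two-value input, importance oracle", {
  # duplicate-pixel degenerate input with two distinct pixel values
  X2 <- matrix(rep(c(1, 9), each = 200), 400, 3)
  run2 <- toy_run(20, 20, X2)
  km2 <- spatial_kmeans(run2, k = 2, smooth_scale = 0, seed = 1)
  expect_identical(sort(unique(km2$mask$labels)), c("comp1", "comp2"))
  expect_true(all(table(km2$mask$labels) == 200))
  expect_error(spatial_kmeans(toy_run(2, 1, matrix(1:2, 2, 1)), k = 5), "k")
  # importance reproduces a brute-force variance decomposition (5 features)
  set.seed(31)
  X <- matrix(stats::rnorm(200 * 5, 10, 1), 200, 5)
  left <- grid_coords(20, 10)[, 1] < 10
  X[left, 2] <- X[left, 2] + 5
  run <- toy_run(20, 10, X)
  km <- spatial_kmeans(run, k = 2, smooth_scale = 0, seed = 1)
  assign <- km$mask$labels
  Xs <- scale(X)
  brute <- sapply(1:5, function(f) {
    tot <- sum((Xs[, f] - mean(Xs[, f]))^2)
    within <- sum(tapply(seq_len(200), assign, function(ii) {
      sum((Xs[ii, f] - mean(Xs[ii, f]))^2)
    }))
    1 - within / tot
  })
  expect_equal(km$importance, brute, tolerance = 1e-10, ignore_attr = TRUE)
  expect_identical(km$mask$source, "multivariate")
  expect_equal(km$features_consumed, run$mz)
})

test_that("shrunken centroids: limits and discriminative-feature recovery", {
  set.seed(11)
  n <- 400; F <- 50
  X <- matrix(stats::rnorm(n * F, 10, 1), n, F)
  right <- grid_coords(20, 20)[, 1] >= 10
  for (f in c(5, 20, 35)) X[right, f] <- X[right, f] + 6
  run <- toy_run(20, 20, pmax(X, 0))
  # s = 0, smooth = 0 matches spatial k-means on a separable toy
  sc0 <- shrunken_centroids_segment(run, k = 2, shrinkage_s = 0,
                                    smooth_scale = 0, seed = 1)
  km <- spatial_kmeans(run, k = 2, smooth_scale = 0, seed = 1)
  a <- mean((sc0$mask$labels == "comp1") == (km$mask$labels == "comp1"))
  expect_gte(max(a, 1 - a), 0.99)
  # s large: all importance zero, degenerate single cluster
  big <- shrunken_centroids_segment(run, k = 2, shrinkage_s = 50, seed = 1)
  expect_true(big$degenerate)
  expect_true(all(big$importance == 0))
  expect_identical(unique(big$mask$labels), "comp1")
  # top-3 importance identifies the 3 truly discriminative features
  sc <- shrunken_centroids_segment(run, k = 2, shrinkage_s = 1,
                                   smooth_scale = 2, seed = 1)
  expect_setequal(order(-sc$importance)[1:3], c(5, 20, 35))
})

test_that("data-driven masks always record the features they consumed", {
  bl <- make_blob_run(seed = 2)
  seg <- univariate_spatial_gmm(bl$run, 700, k = 2)
  expect_gt(length(seg$mask$features_consumed), 0)
  expect_error(roi_mask(c("a", "b"), source = "multivariate"), "consumed")
})
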