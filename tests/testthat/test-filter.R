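# Step 2: filtering, isotope clustering, aggregation, ledger conservation.

# experiment with per-feature constant-ish images whose pooled nonzero mean
# and SD are controlled exactly through the supplied matrix
status_from_matrix <- function(ints) {
  run <- toy_run(nrow(ints), 1, ints, run_id = "r1")
  e <- toy_experiment(list(run))
  list(exp = e, status = feature_status_init(e))
}

test_that("non-specific filter drops only the low-mean AND low-SD feature", {
  # four features with (mean, SD) = (1,1), (2,10), (10,2), (10,10):
  # the type-7 25th percentiles of the means {1,2,10,10} and SDs
  # {1,2,10,10} are both 1.75, so only (1,1) falls strictly below both
  # (strict inequality: values "below" the percentile)
  run <- toy_run(2, 2, matrix(1, 4, 4))
  e <- toy_experiment(list(run))
  st <- feature_status_init(e)
  st$mean <- c(1, 2, 10, 10)
  st$sd <- c(1, 10, 2, 10)
  expect_equal(stats::quantile(st$mean, 0.25, names = FALSE), 1.75)
  out <- nonspecific_filter(st, q = 0.25)
  expect_identical(out$retained, c(FALSE, TRUE, TRUE, TRUE))
  expect_identical(out$drop_reason[1], "low_signal")
  # AND logic: (2,10) has low mean but high SD, (10,2) the reverse -> kept
  # q = 0 drops nothing
  expect_true(all(nonspecific_filter(st, q = 0)$retained))
})

test_that("step-2 filters are blind to condition labels", {
  set.seed(6)
  runs <- lapply(1:4, function(i) {
    toy_run(6, 6, matrix(stats::rexp(36 * 5, 1 / 10), 36, 5),
            run_id = paste0("r", i))
  })
  e1 <- toy_experiment(runs, conditions = c("A", "A", "B", "B"))
  e2 <- toy_experiment(runs, conditions = c("B", "A", "B", "A"))
  s1 <- nonspecific_filter(feature_status_init(e1), 0.25)
  s2 <- nonspecific_filter(feature_status_init(e2), 0.25)
  expect_identical(s1$retained, s2$retained)
})

test_that("ROI sparsity filter follows the strict any-run rule", {
  # feature sparsities per run engineered as (0.1, 0.1, 0.3), all-zero
  # sparsity, and exactly 0.25
  mk_run <- function(id, sp) {
    n <- 20
    v1 <- rep(1, n); v1[seq_len(sp * n)] <- 0          # target feature
    v2 <- rep(2, n)                                     # sparsity 0
    v3 <- rep(3, n); v3[seq_len(0.25 * n)] <- 0         # exactly 0.25
    toy_run(20, 1, cbind(v1, v2, v3), run_id = id)
  }
  runs <- list(mk_run("r1", 0.1), mk_run("r2", 0.1), mk_run("r3", 0.3))
  e <- toy_experiment(runs)
  masks <- lapply(runs, function(r) roi_mask(rep("roi", 20), "external"))
  names(masks) <- c("r1", "r2", "r3")
  st <- roi_sparsity_filter(e, feature_status_init(e), masks, "roi",
                            max_sparsity = 0.25)
  expect_identical(st$retained, c(FALSE, TRUE, TRUE))  # 0.3 in r3 drops f1
  expect_equal(st$max_roi_sparsity, c(0.3, 0, 0.25))
  expect_identical(st$drop_reason[1], "high_sparsity")
})

test_that("isotope clustering joins mass-shifted, spatially similar features", {
  set.seed(41)
  n <- 100
  base <- stats::rexp(n, 1 / 30)
  noise1 <- stats::rexp(n, 1 / 30)
  noise2 <- stats::rexp(n, 1 / 30)
  # features: monoisotopic + 1.00336 with the same image (cluster of 2);
  # a pair with the right gap but independent images (singletons);
  # a triplet at +1.00336 and +2.00672 with correlated images
  mz <- c(900, 901.00336, 1200, 1201.00336, 1500, 1501.00336, 1502.00672)
  ints <- cbind(base, base * 0.6,
                noise1, noise2,
                base + 5, (base + 5) * 0.5, (base + 5) * 0.2)
  run <- msi_run("iso", grid_coords(10, 10), mz, ints)
  e <- toy_experiment(list(run))
  st <- cluster_related_features(e, feature_status_init(e),
                                 min_similarity = 0.9)
  cid <- st$cluster_id
  expect_identical(cid[1], cid[2])
  expect_gt(cid[1], 0L)
  expect_identical(cid[3], 0L)
  expect_identical(cid[4], 0L)
  expect_identical(cid[5], cid[6])
  expect_identical(cid[6], cid[7])
  expect_false(cid[5] == cid[1])
  # brute-force connected-component oracle over all pairs
  edges <- matrix(FALSE, 7, 7)
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  for (i in 1:6) for (j in (i + 1):7) {
    dm <- mz[j] - mz[i]
    ok_mass <- any(abs(dm - (1:3) * 1.00336) <= 20e-6 * mz[j])
    if (ok_mass && cos(ints[, i], ints[, j]) >= 0.9) {
      edges[i, j] <- edges[j, i] <- TRUE
    }
  }
  g_comp <- seq_len(7)
  for (it in 1:7) for (i in 1:7) for (j in 1:7) {
    if (edges[i, j]) g_comp[c(i, j)] <- min(g_comp[c(i, j)])
  }
  for (i in 1:7) for (j in 1:7) {
    same_pkg <- cid[i] > 0 && cid[i] == cid[j]
    expect_identical(same_pkg && i != j,
                     g_comp[i] == g_comp[j] && i != j)
  }
})

test_that("aggregation keeps the most intense member, ties to lower m/z", {
  n <- 50
  ints <- cbind(rep(100, n), rep(30, n),     # cluster 1: A wins
                rep(20, n), rep(20, n))      # cluster 2: tie -> lower mz
  run <- msi_run("agg", grid_coords(10, 5),
                 c(900, 901.00336, 1100, 1101.00336), ints)
  e <- toy_experiment(list(run))
  st <- cluster_related_features(e, feature_status_init(e),
                                 min_similarity = 0.5)
  out <- aggregate_clusters(e, st)
  expect_identical(out$status$retained, c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(out$status$drop_reason[c(2, 4)],
                   rep("non_representative", 2))
  expect_equal(out$experiment$runs[[1]]$mz, c(900, 1100))
  # reduced matrix is a column subset of the input (no invented values)
  expect_identical(out$experiment$runs[[1]]$intensities, ints[, c(1, 3)])
})

test_that("all-singleton clustering leaves the feature count unchanged", {
  set.seed(3)
  run <- toy_run(5, 5, matrix(stats::rexp(25 * 4, 1 / 10), 25, 4))
  e <- toy_experiment(list(run))
  st <- cluster_related_features(e, feature_status_init(e))
  expect_true(all(st$cluster_id == 0))
  out <- aggregate_clusters(e, st)
  expect_identical(ncol(out$experiment$runs[[1]]$intensities), 4L)
})

test_that("planted isotope pairs are removed and monoisotopic peaks kept", {
  set.seed(17)
  n <- 100; n_pairs <- 20; n_free <- 60
  imgs <- matrix(stats::rexp(n * n_pairs, 1 / 40), n, n_pairs)
  mz_mono <- seq(800, by = 7, length.out = n_pairs)
  mz <- c(mz_mono, mz_mono + 1.00336,
          seq(1600, by = 7, length.out = n_free))
  ints <- cbind(imgs, imgs * 0.55,
                matrix(stats::rexp(n * n_free, 1 / 40), n, n_free))
  o <- order(mz)
  run <- msi_run("planted", grid_coords(10, 10), mz[o], ints[, o])
  e <- toy_experiment(list(run))
  st <- cluster_related_features(e, feature_status_init(e),
                                 min_similarity = 0.95)
  out <- aggregate_clusters(e, st)
  expect_identical(sum(out$status$retained), as.integer(n_pairs + n_free))
  # every planted monoisotopic m/z is retained (it is the intense member)
  kept <- out$status$mz[out$status$retained]
  expect_true(all(mz_mono %in% kept))
})

test_that("the feature ledger conserves counts across Step 2", {
  set.seed(23)
  sim <- simulate_experiment(sim1_config(seed = 23, dims = c(20, 20),
                                         n_features = 60,
                                         n_per_condition = 2))
  e <- sim$experiment
  st <- feature_status_init(e)
  st <- mark_consumed(st, e$runs[[1]]$mz[1])      # marker feature
  st <- nonspecific_filter(st, 0.25)
  st <- roi_sparsity_filter(e, st, label = "roi", max_sparsity = 0.25)
  st <- cluster_related_features(e, st)
  out <- aggregate_clusters(e, st)
  led <- status_ledger(out$status)
  expect_identical(led$n[led$stage == "input"],
                   sum(led$n[led$stage != "input"]))
  expect_true(all(out$status$retained == (out$status$drop_reason == "none")))
})
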