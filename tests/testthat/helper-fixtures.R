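# Fixtures are built in code at test time; nothing binary is stored.

grid_coords <- msidiff:::grid_coords

# A tiny rectangular run with given intensity matrix (pixels in grid order).
toy_run <- function(W, H, intensities, mz = NULL, run_id = "toy") {
  if (is.null(mz)) mz <- seq(600, by = 1.5, length.out = ncol(intensities))
  msi_run(run_id, grid_coords(W, H), mz, intensities)
}

# Single-feature runs from plain value vectors (one pixel per value).
vector_run <- function(values, run_id, mz = 500) {
  msi_run(run_id, cbind(x = seq_along(values) - 1L, y = 0L), mz,
          cbind(values))
}

toy_experiment <- function(runs, conditions = NULL, tissues = NULL,
                           subjects = NULL) {
  n <- length(runs)
  ids <- vapply(runs, function(r) r$run_id, character(1))
  msi_experiment(runs, data.frame(
    run_id = ids,
    subject = if (is.null(subjects)) paste0("s", seq_len(n)) else subjects,
    condition = if (is.null(conditions)) rep("A", n) else conditions,
    tissue = if (is.null(tissues)) rep("T1", n) else tissues))
}

# Balanced ROI-summary generator: I subjects per condition, J = 2 conditions,
# K = 2 tissues, with known variance components and cell effects. Generates
# the modelling unit directly (fast path for diffstat tests).
balanced_summary <- function(seed, I = 4, var_subject = 4, var_tech = 1,
                             cond_effect = 0, tissue_effect = 0,
                             inter_effect = 0, n_features = 1, mu0 = 100) {
  set.seed(seed)
  subj <- sprintf("s%02d", seq_len(2 * I))
  cond <- rep(c("A", "B"), each = I)
  rows <- expand.grid(subject = subj, tissue = c("T1", "T2"),
                      stringsAsFactors = FALSE)
  rows$condition <- cond[match(rows$subject, subj)]
  rows$run_id <- paste0(rows$subject, "-", rows$tissue)
  out <- lapply(seq_len(n_features), function(f) {
    b <- stats::rnorm(2 * I, 0, sqrt(var_subject))
    names(b) <- subj
    y <- mu0 + b[rows$subject] +
      cond_effect * (rows$condition == "A") +
      tissue_effect * (rows$tissue == "T1") +
      inter_effect * (rows$condition == "A") * (rows$tissue == "T1") +
      stats::rnorm(nrow(rows), 0, sqrt(var_tech))
    data.frame(mz = 600 + f, run_id = rows$run_id, subject = rows$subject,
               condition = rows$condition, tissue = rows$tissue,
               roi = "roi", ybar = as.numeric(y), n_pixels = 10L)
  })
  res <- do.call(rbind, out)
  class(res) <- c("roi_summary", "data.frame")
  res
}

# Agreement of a two-class labelling with a logical truth, up to label swap.
two_class_agreement <- function(labels, truth) {
  a <- mean((labels == labels[1]) == truth)
  max(a, 1 - a)
}
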