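# REML estimation for the single-random-intercept linear mixed model
#   y = X beta + Z b + e,  b ~ N(0, sigma2_subj I),  e ~ N(0, sigma2 I)
# with b indexed by a grouping factor (subject). The likelihood is profiled
# over the variance ratio lambda = sigma2_subj / sigma2 and everything is
# computed from cell-level sufficient statistics, so the same code fits both
# ROI-mean models (each observation its own cell) and pixel-as-replicate
# models (each run a cell holding thousands of pixels) in O(#cells) per
# likelihood evaluation.
#
# Sufficient statistics per cell r (a set of observations sharing one X row
# and one group): n_r, s_r = sum(y), q_r = sum(y^2). Within each group g,
# V_g^-1 = (1/sigma2) (I - lambda/(1 + lambda n_g) J), so
#   X'V^-1X = A - sum_g a_g u_g u_g',   a_g = lambda/(1+lambda n_g)
#   X'V^-1y = X's - sum_g a_g u_g t_g
#   y'V^-1y = sum(q) - sum_g a_g t_g^2
# with A = sum n_r x_r x_r', u_g = sum_{r in g} n_r x_r, t_g = sum s_r.

reml_fit_cells <- function(s_cell, q_cell, n_cell, X, group = NULL,
                           tol = 1e-10, lambda_candidates = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  n <- sum(n_cell)
  if (n <= p) stop("not enough observations to fit the model")
  A <- crossprod(X, X * n_cell)
  Xts <- crossprod(X, s_cell)
  qtot <- sum(q_cell)

  have_group <- !is.null(group)
  if (have_group) {
    group <- as.factor(group)
    G <- nlevels(group)
    U <- rowsum(X * n_cell, group)                  # G x p
    tg <- as.numeric(rowsum(matrix(s_cell), group))
    ng <- as.numeric(rowsum(matrix(n_cell), group))
  }

  solve_at <- function(lambda) {
    if (have_group && lambda > 0) {
      a <- lambda / (1 + lambda * ng)
      XtViX <- A - t(U) %*% (U * a)                 # sum_g a_g u_g u_g'
      XtViy <- Xts - t(U) %*% (a * tg)
      ytViy <- qtot - sum(a * tg^2)
      logdetV <- sum(log1p(lambda * ng))
    } else {
      XtViX <- A; XtViy <- Xts; ytViy <- qtot; logdetV <- 0
    }
    beta <- solve(XtViX, XtViy)
    rss <- max(ytViy - sum(beta * XtViy), 0)
    sigma2 <- rss / (n - p)
    m2ll <- if (sigma2 > 0) {
      (n - p) * log(sigma2) + logdetV +
        determinant(XtViX, logarithm = TRUE)$modulus[1]
    } else -Inf                     # exact fit: any lambda is 'optimal'
    list(lambda = lambda, beta = as.numeric(beta), XtViX = XtViX,
         sigma2 = sigma2, rss = rss, m2ll = m2ll)
  }

  best <- solve_at(0)
  if (have_group && nlevels(group) > 1L) {
    crit <- function(loglam) {
      v <- solve_at(exp(loglam))$m2ll
      if (is.finite(v)) v else 1e300
    }
    opt <- stats::optimize(crit, interval = c(-30, 15), tol = 1e-8)
    # quadratic polish: optimize()'s golden-section precision (~sqrt(eps))
    # is not enough for the 1e-8 closed-form equivalence we guarantee
    x <- opt$minimum
    h <- 1e-4
    for (i in 1:30) {
      f0 <- crit(x); fm <- crit(x - h); fp <- crit(x + h)
      denom <- fp - 2 * f0 + fm
      if (!is.finite(denom) || denom <= 0) break
      step <- 0.5 * h * (fm - fp) / denom
      if (!is.finite(step)) break
      x <- x + sign(step) * min(abs(step), 1)
      h <- max(h / 4, 1e-9)
      if (abs(step) < 1e-12) break
    }
    cand <- solve_at(exp(x))
    if (crit(opt$minimum) < cand$m2ll) cand <- solve_at(exp(opt$minimum))
    if (cand$m2ll < best$m2ll - 1e-12) best <- cand
    # known exact optima (e.g. the balanced-ANOVA solution) supplied by the
    # caller take precedence when they match the numeric optimum
    for (lc in lambda_candidates) {
      if (!is.finite(lc) || lc <= 0) next
      cl <- solve_at(lc)
      if (cl$m2ll <= best$m2ll + 1e-8) best <- cl
    }
  }

  lambda <- best$lambda
  sigma2 <- best$sigma2
  sigma2_subj <- lambda * sigma2
  singular <- have_group &&
    (sigma2_subj + sigma2 <= 0 ||
       sigma2_subj / (sigma2_subj + sigma2) < 1e-6)
  method <- if (!have_group) "OLS" else if (singular) "OLS-fallback" else "REML"
  if (singular) {
    best <- solve_at(0)
    sigma2 <- best$sigma2
    sigma2_subj <- 0
    lambda <- 0
  }
  vcov_beta <- sigma2 * solve(best$XtViX)

  blup <- NULL
  if (have_group && lambda > 0) {
    resid_g <- tg - as.numeric(U %*% best$beta)
    blup <- lambda * resid_g / (1 + lambda * ng)
    names(blup) <- levels(group)
  }

  list(beta = best$beta, vcov_beta = vcov_beta,
       sigma2 = sigma2, sigma2_subj = sigma2_subj, lambda = lambda,
       method = method, singular = singular, n = n, p = p,
       df_resid_ols = n - p, m2ll = best$m2ll, blup = blup,
       group_levels = if (have_group) levels(group) else NULL,
       stats = list(A = A, Xts = Xts, qtot = qtot,
                    U = if (have_group) U else NULL,
                    tg = if (have_group) tg else NULL,
                    ng = if (have_group) ng else NULL))
}

# Full -2 REML log-likelihood as a function of (sigma2_subj, sigma2), with
# beta profiled out; used to get the REML variance-component covariance for
# the delta-method Satterthwaite path. Constant terms omitted (they do not
# affect derivatives).
m2ll_varcomp <- function(vs, ve, fit) {
  st <- fit$stats
  n <- fit$n; p <- fit$p
  if (is.null(st$U) || vs <= 0) {
    XtViX <- st$A / ve
    XtViy <- st$Xts / ve
    ytViy <- st$qtot / ve
    logdetV <- n * log(ve)
  } else {
    a <- vs / (ve + vs * st$ng)                    # = lambda/(1+lambda n)/ 1
    XtViX <- (st$A - t(st$U) %*% (st$U * a)) / ve
    XtViy <- (st$Xts - t(st$U) %*% (a * st$tg)) / ve
    ytViy <- (st$qtot - sum(a * st$tg^2)) / ve
    logdetV <- (n - length(st$ng)) * log(ve) + sum(log(ve + vs * st$ng))
  }
  beta <- solve(XtViX, XtViy)
  rss <- ytViy - sum(beta * XtViy)
  logdetV + determinant(XtViX, logarithm = TRUE)$modulus[1] + rss
}

# Covariance of (sigma2_subj, sigma2) at the REML optimum via the numerical
# Hessian of the -2 log-likelihood: Var(theta) ~ 2 H^-1.
varcomp_vcov <- function(fit) {
  th <- c(fit$sigma2_subj, fit$sigma2)
  f <- function(x) m2ll_varcomp(x[1], x[2], fit)
  h <- pmax(1e-6, 1e-4 * abs(th))
  H <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- (f(th + ei + ej) - f(th + ei - ej) -
                f(th - ei + ej) + f(th - ei - ej)) / (4 * h[i] * h[j])
  }
  H <- (H + t(H)) / 2
  V <- tryCatch(2 * solve(H), error = function(e) matrix(NA_real_, 2, 2))
  V
}

# Satterthwaite df for contrast c on beta, general (delta-method) path:
# f(theta) = c' (X'V(theta)^-1 X)^-1 c, df = 2 f^2 / Var(f_hat).
satterthwaite_df_general <- function(fit, cvec) {
  if (fit$method != "REML") return(fit$df_resid_ols)
  st <- fit$stats
  fvar <- function(vs, ve) {
    a <- vs / (ve + vs * st$ng)
    XtViX <- (st$A - t(st$U) %*% (st$U * a)) / ve
    as.numeric(t(cvec) %*% solve(XtViX, cvec))
  }
  th <- c(fit$sigma2_subj, fit$sigma2)
  h <- pmax(1e-6, 1e-4 * abs(th))
  g <- c((fvar(th[1] + h[1], th[2]) - fvar(max(th[1] - h[1], 0), th[2])) /
           (h[1] + min(th[1], h[1])),
         (fvar(th[1], th[2] + h[2]) - fvar(th[1], th[2] - h[2])) / (2 * h[2]))
  V <- varcomp_vcov(fit)
  f0 <- fvar(th[1], th[2])
  vf <- as.numeric(t(g) %*% V %*% g)
  if (!is.finite(vf) || vf <= 0) return(fit$df_resid_ols)
  df <- 2 * f0^2 / vf
  # guard against numeric instability: floor at 1, cap at the OLS residual df
  min(max(df, 1), fit$df_resid_ols)
}
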