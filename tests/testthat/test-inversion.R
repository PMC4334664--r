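test_that("log_likelihood matches hand and brute-force computations", {
  # zero residual under unit precision
  expect_identical(log_likelihood(1:3, 1:3, rep(1, 3), include_const = FALSE), 0)
  expect_equal(log_likelihood(1:3, 1:3, rep(1, 3)), -1.5 * log(2 * pi))
  # scalar case y = 1, g = 0, precision 2: -1/2 * 2 + 1/2 * ln 2
  expect_equal(log_likelihood(1, 0, 2, include_const = FALSE),
               -1 + 0.5 * log(2))
  expect_equal(log_likelihood(1, 0, 2),
               dnorm(1, 0, 1 / sqrt(2), log = TRUE))
  # doubling residuals quadruples the quadratic term
  y <- c(0.3, -0.2, 0.7); p <- c(2, 1, 3)
  l1 <- log_likelihood(y, 0 * y, p, include_const = FALSE)
  l2 <- log_likelihood(2 * y, 0 * y, p, include_const = FALSE)
  ld <- 0.5 * sum(log(p))
  expect_equal(l2 - ld, 4 * (l1 - ld))
  # matrix and vector precision agree; singular precision rejected
  expect_equal(log_likelihood(y, 0 * y, diag(p)), log_likelihood(y, 0 * y, p))
  expect_error(log_likelihood(y, y, c(1, 0, 1)), "singular")
})

test_that("variational Laplace recovers the exact linear-Gaussian posterior", {
  set.seed(42)
  X <- matrix(rnorm(12), 6, 2)
  truth <- c(0.5, -0.3)
  y <- drop(X %*% truth)
  pm <- c(0, 0); pv <- c(1, 1)
  res <- vl_fit(y, function(th) drop(X %*% th), pm, pv,
                factor(rep("a", 6)), tol = 1e-8)
  Pi <- exp(unname(res$lambda))
  S <- solve(Pi * crossprod(X) + diag(1, 2))
  mu <- drop(S %*% (Pi * crossprod(X, y)))
  expect_equal(unname(res$mu), mu, tolerance = 1e-5)
  expect_equal(unname(res$Sigma), S, tolerance = 1e-4)
  expect_true(res$converged)
})

test_that("free energy ascends and decomposes into accuracy minus complexity", {
  d <- generate_dataset(sample_prior(seed = 9), tiny_grid,
                        log_precision = 7, seed = 10)
  fit <- fit_csd(d$csd)
  expect_true(fit$converged)
  expect_true(all(diff(fit$trace) > -1e-3))
  expect_equal(fit$F, fit$accuracy - fit$complexity,
               tolerance = 1e-6 * abs(fit$F))
  # posterior covariance is symmetric positive semidefinite
  ev <- eigen(fit$Sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10 * max(ev)))
})

test_that("a degenerate prior pins the posterior at the prior mean", {
  pr <- cmc_priors()
  pr$var[] <- 0
  d <- generate_dataset(NULL, tiny_grid, log_precision = 7, seed = 2)
  fit <- fit_csd(d$csd, priors = pr)
  expect_identical(unname(fit$mu), rep(0, length(pr$mean)))
  expect_true(fit$converged)
})

test_that("the Laplace posterior matches dense-grid Bayes on a two-parameter toy", {
  gt <- function(th) c(exp(th[1]), th[1] + 0.3 * th[2]^2 + th[2], 2 * th[2])
  yobs <- gt(c(0.3, -0.2))
  pv <- c(0.5, 0.5)
  res <- vl_fit(yobs, gt, c(0, 0), pv, factor(rep("a", 3)),
                hyper_mean = 6, hyper_var = 1/64, tol = 1e-6)
  lam <- unname(res$lambda)
  g1 <- seq(-1, 1, length.out = 601)
  g2 <- seq(-1, 1, length.out = 601)
  lp <- outer(g1, g2, Vectorize(function(a, b) {
    e <- yobs - gt(c(a, b))
    -0.5 * exp(lam) * sum(e^2) - 0.5 * sum(c(a, b)^2 / pv)
  }))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  m <- c(sum(rowSums(p) * g1), sum(colSums(p) * g2))
  s <- c(sqrt(sum(rowSums(p) * (g1 - m[1])^2)),
         sqrt(sum(colSums(p) * (g2 - m[2])^2)))
  expect_lt(max(abs(unname(res$mu) - m) / s), 0.05)
  expect_lt(max(abs(sqrt(diag(res$Sigma)) / s - 1)), 0.05)
})

test_that("reduced log evidence equals the pairwise block of the accuracy", {
  d <- generate_dataset(sample_prior(seed = 21), tiny_grid,
                        log_precision = 7, seed = 22)
  fit <- fit_csd(d$csd)
  feats <- csd_features(d$csd)
  pred <- csd_features(fit$predicted)
  total <- 0
  for (pr in list(c(1, 1), c(1, 2), c(2, 2))) {
    fij <- reduced_log_evidence(fit, d$csd, pr)
    lab <- paste(pr[1], pr[2], sep = "_")
    sel <- feats$block == lab
    Pi <- exp(unname(fit$lambda[lab]))
    expect_equal(fij,
                 log_likelihood(feats$y[sel], pred$y[sel], rep(Pi, sum(sel)),
                                include_const = FALSE))
    total <- total + fij
  }
  # summing pairwise blocks recovers the residual part of the accuracy:
  # what remains is the expected-curvature correction, which is nonpositive
  n <- length(feats$y)
  qcorr <- fit$accuracy + 0.5 * n * log(2 * pi) - total
  expect_lt(qcorr, 1e-6)
  expect_error(reduced_log_evidence(fit, d$csd, c(1, 5)), "invalid")
})

test_that("a perfect fit on a pair leaves only the log-determinant term", {
  fit <- quick_fit()
  d <- fit$predicted # observed equals predicted exactly
  f12 <- reduced_log_evidence(fit, d, c(1, 2))
  n12 <- sum(csd_features(d)$block == "1_2")
  expect_equal(f12, 0.5 * n12 * log(exp(unname(fit$lambda["1_2"]))),
               tolerance = 1e-8)
})

test_that("identical models on identical data are indistinguishable and evidence pools", {
  d <- generate_dataset(NULL, tiny_grid, log_precision = 7, seed = 5)
  f1 <- fit_csd(d$csd, "veridical")
  f2 <- fit_csd(d$csd, "veridical")
  expect_equal(f1$F - f2$F, 0, tolerance = 1e-9)
  cmp1 <- compare_models(d$csd)
  d2 <- generate_dataset(NULL, tiny_grid, log_precision = 7, seed = 6)
  cmp2 <- compare_models(d2$csd)
  pooled <- pool_evidence(list(cmp1, cmp2))
  expect_equal(pooled$dF, cmp1$dF + cmp2$dF)
  expect_equal(pooled$d_reduced, cmp1$d_reduced + cmp2$d_reduced)
})

test_that("posterior widths on extrinsic gains grow with observation noise", {
  # under an adaptive precision hyperprior the estimated log precision
  # tracks the true noise level and credible intervals widen accordingly
  cf <- cmc_config(hyper_var = 1)
  med <- c()
  lams <- c()
  for (lp in c(7, 2)) {
    w <- c(); lam <- c()
    for (k in 1:3) {
      th <- sample_prior(seed = 500 + k)
      d <- generate_dataset(th, tiny_grid, log_precision = lp, seed = 600 + k)
      f <- fit_csd(d$csd, config = cf)
      w <- c(w, sqrt(diag(f$Sigma))[c("a_fwd", "a_bwd_spc", "a_bwd_ii")])
      lam <- c(lam, f$lambda)
    }
    med <- c(med, median(w))
    lams <- c(lams, median(lam))
  }
  expect_gt(med[2], med[1])   # more noise, wider intervals
  expect_lt(lams[2], lams[1]) # and lower estimated log precision
})

test_that("selection accuracy does not fall as the log precision rises", {
  counts <- vapply(c(1, 4, 7), function(lp) {
    ok <- 0
    for (k in 1:5) {
      th <- sample_prior(seed = 300 + k)
      d <- generate_dataset(th, tiny_grid, log_precision = lp, seed = 400 + k)
      ok <- ok + (compare_models(d$csd)$selected == "veridical")
    }
    ok
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gte(counts[3], 4)
})
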