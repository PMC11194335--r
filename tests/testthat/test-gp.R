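# GBLUP models: Gibbs sampler vs closed-form oracle, variance
# decomposition, posterior summaries.

test_that("variance-explained ratio follows the footnote formula", {
  # worked examples with published posterior-mean components
  r1 <- variance_r2(variance_components(sigma2_u0 = 0.288, sigma2_e = 0.111,
                                        model = "single_env"))
  expect_equal(round(r1$r2, 3), 0.722)
  r2 <- variance_r2(variance_components(sigma2_u0 = 0.206, sigma2_e = 0.854,
                                        model = "single_env"))
  expect_equal(round(r2$r2, 3), 0.194)
  # degenerate and error cases
  r0 <- variance_r2(variance_components(0, NULL, 1, "single_env"))
  expect_equal(r0$r2, 0)
  expect_error(variance_r2(variance_components(0, NULL, 0, "single_env")),
               "zero")
  # fractions always sum to one
  rx <- variance_r2(variance_components(0.3, c(a = 0.1, b = 0.5), 0.2, "mxe"))
  expect_equal(rx$frac_main + rx$frac_specific + rx$frac_residual,
               c(1, 1), tolerance = 1e-12)
  expect_identical(rx$environment, c("a", "b"))
})

test_that("R2 is monotone in the specific and residual variances", {
  grid <- seq(0, 1, by = 0.1)
  r_uj <- vapply(grid, function(u) variance_r2(
    variance_components(0.3, c(e1 = u, e2 = u), 0.4, "mxe"))$r2[1],
    numeric(1))
  expect_true(all(diff(r_uj) > 0))
  r_e <- vapply(grid + 0.05, function(e) variance_r2(
    variance_components(0.3, c(e1 = 0.2, e2 = 0.2), e, "mxe"))$r2[1],
    numeric(1))
  expect_true(all(diff(r_e) < 0))
})

test_that("MCMC defaults follow the reference settings", {
  st <- mcmc_settings()
  expect_identical(st$n_iter, 25000L)
  expect_identical(st$burn_in, 2500L)
  expect_error(mcmc_settings(n_iter = 100, burn_in = 200), "burn_in")
})

test_that("identical seeds give bit-identical chains", {
  sim <- quick_dataset(n = 40, p = 60, seed = 3)
  st <- fast_mcmc(n_iter = 400, burn_in = 100, seed = 5)
  f1 <- fit_mxe(sim$data, st)
  f2 <- fit_mxe(sim$data, st)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$b0, f2$b0)
  f3 <- fit_mxe(sim$data, fast_mcmc(n_iter = 400, burn_in = 100, seed = 6))
  expect_false(identical(f1$samples, f3$samples))
})

test_that("GEBVs reproduce the marker-effect identity u = Xb", {
  sim <- quick_dataset(n = 40, p = 60, seed = 4)
  fit <- fit_mxe(sim$data, fast_mcmc(n_iter = 400, burn_in = 100))
  expect_lt(max(abs(fit$u0 - drop(sim$data$X$X %*% fit$b0))), 1e-8)
  expect_lt(max(abs(fit$u1 - sim$data$X$X %*% fit$bj)), 1e-8)
})

test_that("an all-zero phenotype vector yields near-zero GEBVs", {
  X <- strip_mm(rand_marker_matrix(30, 40, seed = 2))
  y <- setNames(rep(0, 30), rownames(X$X))
  fit <- fit_single_env(y, X, fast_mcmc(n_iter = 600, burn_in = 100))
  expect_lt(max(abs(fit$u0)), 1e-3)
  expect_lt(fit$varcomps$sigma2_u0, 1e-3)
})

test_that("posterior-mean GEBVs match closed-form GBLUP at fixed variances
          for all three models", {
  sim <- quick_dataset(n = 60, p = 100, seed = 5)
  G <- compute_grm(sim$data$X)
  st <- fast_mcmc(n_iter = 3000, burn_in = 500, seed = 13)

  vc_m <- variance_components(0.4, c(0.2, 0.2), 0.4, "mxe")
  fm <- fit_gp(sim$data, "mxe", st, fixed_varcomps = vc_m)
  om <- gblup_oracle(sim$data, G, vc_m)
  expect_gt(cor(fm$u0, om$u0), 0.99)
  expect_gt(cor(as.vector(predict(fm)), as.vector(om$fitted)), 0.995)

  vc_a <- variance_components(0.5, NULL, 0.5, "across_env")
  fa <- fit_gp(sim$data, "across_env", st, fixed_varcomps = vc_a)
  oa <- gblup_oracle(sim$data, G, vc_a)
  expect_gt(cor(fa$u0, oa$u0), 0.99)

  y1 <- sim$data$Y[, 1]
  vc_s <- variance_components(0.5, NULL, 0.5, "single_env")
  fs <- fit_single_env(y1, sim$data$X, st, fixed_varcomps = vc_s)
  ds <- multienv_dataset(matrix(y1, ncol = 1,
                                dimnames = list(names(y1), "e1")), sim$data$X)
  os <- gblup_oracle(ds, G, vc_s)
  expect_gt(cor(fs$u0, os$u0), 0.99)
})

test_that("duplicated environments reduce the across-env fit to single-env", {
  X <- strip_mm(rand_marker_matrix(80, 80, seed = 6))
  set.seed(6)
  b <- rnorm(80, 0, sqrt(0.5 / 80))
  y1 <- drop(X$X %*% b) + rnorm(80, 0, sqrt(0.4))
  Y <- cbind(e1 = y1, e2 = y1)
  rownames(Y) <- rownames(X$X)
  dat <- multienv_dataset(Y, X)
  st <- fast_mcmc(n_iter = 6000, burn_in = 1000, seed = 8)
  # at fixed variance components the two fits target the same posterior
  vc2 <- variance_components(0.5, NULL, 0.4, "across_env")
  vc1 <- variance_components(0.5, NULL, 0.2, "single_env")
  fa_fix <- fit_gp(dat, "across_env", st, fixed_varcomps = vc2)
  fs_fix <- fit_single_env(setNames(y1, rownames(X$X)), X, st,
                           fixed_varcomps = vc1)
  # duplicating every record halves the effective residual variance, so the
  # single-environment reference uses half the stacked sigma2_e
  expect_gt(cor(fa_fix$u0, fs_fix$u0), 0.99)
  # with variances estimated, duplication sharpens the posterior but the
  # ranking of accessions is preserved
  fa <- fit_across_env(dat, st)
  fs <- fit_single_env(setNames(y1, rownames(X$X)), X, st)
  expect_gt(cor(fa$u0, fs$u0), 0.95)
})

test_that("the interaction model collapses to shared effects when no
          environment-specific variance was simulated", {
  sim <- quick_dataset(n = 300, p = 150, s2u0 = 0.6, s2uj = 0, s2e = 0.4,
                       seed = 7)
  st <- fast_mcmc(n_iter = 4000, burn_in = 800, seed = 9)
  fm <- fit_mxe(sim$data, st)
  fa <- fit_across_env(sim$data, st)
  # specific variances collapse towards their prior floor, well below the
  # ~0.5 ratio that genuinely interacting data of this size produce ...
  expect_true(all(fm$varcomps$sigma2_uj < 0.35 * fm$varcomps$sigma2_u0))
  # ... and the total genetic signal agrees with the shared-effect fit
  expect_gt(cor(fm$u0 + rowMeans(fm$u1), fa$u0), 0.99)
})

test_that("the sampler recovers a known heritability on simulated data", {
  hats <- vapply(1:5, function(s) {
    X <- strip_mm(rand_marker_matrix(250, 300, seed = 20 + s))
    set.seed(20 + s)
    b <- rnorm(300, 0, sqrt(0.7 / 300))
    y <- setNames(drop(X$X %*% b) + rnorm(250, 0, sqrt(0.3)), rownames(X$X))
    fit <- fit_single_env(y, X, fast_mcmc(n_iter = 2000, burn_in = 400,
                                          seed = s))
    vc <- fit$varcomps
    vc$sigma2_u0 / (vc$sigma2_u0 + vc$sigma2_e)
  }, numeric(1))
  expect_lt(abs(median(hats) - 0.7), 0.1)
})

test_that("gblup_oracle has the textbook closed forms", {
  # single identity kernel with equal variances: u = (y - ybar) / 2
  set.seed(10)
  y <- rnorm(12)
  ids <- sprintf("a%02d", 1:12)
  G <- diag(12); dimnames(G) <- list(ids, ids)
  X <- strip_mm(rand_marker_matrix(12, 5, seed = 10, ids = ids))
  dat <- multienv_dataset(matrix(y, ncol = 1, dimnames = list(ids, "e1")), X)
  o <- gblup_oracle(dat, G, variance_components(1, NULL, 1, "single_env"))
  expect_equal(unname(o$u0), (y - mean(y)) / 2, tolerance = 1e-10)
  # joint rescaling of all variances leaves predictions unchanged
  o2 <- gblup_oracle(dat, G, variance_components(7, NULL, 7, "single_env"))
  expect_equal(o$u0, o2$u0, tolerance = 1e-10)
})

test_that("gblup_oracle matches a hand-built two-environment solve", {
  ids <- c("w", "x", "y", "z")
  G <- matrix(c(1, .5, .2, .1,
                .5, 1, .3, .2,
                .2, .3, 1, .4,
                .1, .2, .4, 1), 4, dimnames = list(ids, ids))
  X <- strip_mm(rand_marker_matrix(4, 3, seed = 11, ids = ids))
  Y <- matrix(c(0.3, -0.1, 0.5, NA, 0.2, NA, -0.4, 0.6), 4, 2,
              dimnames = list(ids, c("e1", "e2")))
  vc <- variance_components(0.5, c(e1 = 0.3, e2 = 0.2), 0.4, "mxe")
  o <- gblup_oracle(multienv_dataset(Y, X), G, vc)
  # direct dense construction, observation by observation
  obs <- which(!is.na(Y), arr.ind = TRUE)
  yv <- Y[obs]
  n <- length(yv)
  V <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    V[i, j] <- 0.5 * G[obs[i, 1], obs[j, 1]]
    if (obs[i, 2] == obs[j, 2])
      V[i, j] <- V[i, j] + c(0.3, 0.2)[obs[i, 2]] * G[obs[i, 1], obs[j, 1]]
    if (i == j) V[i, j] <- V[i, j] + 0.4
  }
  W <- matrix(0, n, 2); W[cbind(1:n, obs[, 2])] <- 1
  Vi <- solve(V)
  mu <- solve(t(W) %*% Vi %*% W, t(W) %*% Vi %*% yv)[, 1]
  alpha <- Vi %*% (yv - W %*% mu)
  u0 <- 0.5 * drop(G[, obs[, 1]] %*% alpha)
  expect_equal(unname(o$mu), unname(mu), tolerance = 1e-10)
  expect_equal(unname(o$u0), unname(u0), tolerance = 1e-10)
  expect_error(gblup_oracle(multienv_dataset(Y, X), G * 0,
                            variance_components(1, c(0, 0), 0, "mxe")),
               "singular")
})

test_that("posterior summaries behave on constant, iid and thinned chains", {
  sim <- quick_dataset(n = 40, p = 50, seed = 12)
  fit <- fit_mxe(sim$data, fast_mcmc(n_iter = 1200, burn_in = 200, seed = 2))
  ps <- posterior_summary(fit)
  expect_true(all(c("mean", "sd", "lower", "upper", "ess") %in% colnames(ps)))
  # constant chain
  fit_const <- fit
  fit_const$samples[, 1] <- 1
  expect_equal(unname(posterior_summary(fit_const)[1, "sd"]), 0)
  # iid normal chain recovers its generating moments within MC error
  set.seed(3)
  fit_iid <- fit
  fit_iid$samples[, 1] <- rnorm(nrow(fit$samples), 2, 0.5)
  ps_iid <- posterior_summary(fit_iid)[1, ]
  expect_lt(abs(ps_iid["mean"] - 2), 4 * 0.5 / sqrt(nrow(fit$samples)))
  expect_lt(abs(ps_iid["sd"] - 0.5), 0.1)
  # thinning that keeps enough draws barely moves the summary
  fit_thin <- fit_mxe(sim$data,
                      fast_mcmc(n_iter = 1200, burn_in = 200, seed = 2,
                                thin = 2))
  expect_equal(posterior_summary(fit_thin)[, "mean"], ps[, "mean"],
               tolerance = 0.15)
  fit$samples <- fit$samples[0, , drop = FALSE]
  expect_error(posterior_summary(fit), "samples")
})

test_that("model preconditions are enforced", {
  sim <- quick_dataset(n = 30, p = 40, seed = 14)
  expect_error(fit_gp(sim$data, "single_env", fast_mcmc(300, 100)),
               "exactly one")
  y1 <- sim$data$Y[, 1, drop = FALSE]
  d1 <- multienv_dataset(y1, sim$data$X)
  expect_error(fit_gp(d1, "mxe", fast_mcmc(300, 100)), "at least 2")
  tiny <- setNames(rnorm(5), rownames(sim$data$X$X)[1:5])
  Xs <- sim$data$X; Xs$X <- Xs$X[1:5, ]
  expect_error(fit_single_env(tiny, Xs, fast_mcmc(300, 100)), "fewer than 10")
})
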