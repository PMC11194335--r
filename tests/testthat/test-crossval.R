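# CV partition construction, predictive ability, bias, sweeps and
# cross-population validation.

acc20 <- sprintf("a%02d", 1:20)
envs2 <- c("e1", "e2")

test_that("CV1 partitions hold the same accessions out of every environment", {
  part <- make_cv1(sprintf("a%02d", 1:10), envs2, test_fraction = 0.3,
                   n_partitions = 8, seed = 2)
  for (m in part$masks) {
    expect_equal(sum(m[, 1]), 3)
    expect_identical(m[, 1], m[, 2])
  }
  # determinism and seed sensitivity
  again <- make_cv1(sprintf("a%02d", 1:10), envs2, 0.3, 8, seed = 2)
  expect_identical(part$masks, again$masks)
  other <- make_cv1(sprintf("a%02d", 1:10), envs2, 0.3, 8, seed = 3)
  expect_false(identical(part$masks, other$masks))
  expect_error(make_cv1(acc20, envs2, 0.001, 5, 1), "empty")
})

test_that("50 CV1 partitions cover essentially every accession", {
  acc <- sprintf("a%03d", 1:100)
  part <- make_cv1(acc, envs2, 0.3, 50, seed = 4)
  tested <- Reduce(`|`, lapply(part$masks, function(m) m[, 1]))
  expect_true(all(tested))
})

test_that("CV2 test sets are disjoint across environments", {
  part <- make_cv2(sprintf("a%02d", 1:10), envs2, 0.3, 10, seed = 5)
  for (m in part$masks) {
    expect_equal(colSums(m), c(e1 = 3, e2 = 3))
    expect_true(all(rowSums(m) <= 1))  # never test in both environments
  }
  # property over seeds and 3 environments
  for (seed in 1:5) {
    p3 <- make_cv2(sprintf("a%02d", 1:30), c("e1", "e2", "e3"), 0.2, 5, seed)
    for (m in p3$masks) expect_true(all(rowSums(m) <= 1))
  }
  # boundary: 2 envs at fraction 0.5 is an exact bipartition
  pb <- make_cv2(sprintf("a%02d", 1:10), envs2, 0.5, 5, seed = 6)
  for (m in pb$masks) expect_true(all(rowSums(m) == 1))
  expect_error(make_cv2(sprintf("a%02d", 1:10), envs2, 0.6, 5, 1),
               "infeasible")
  expect_error(make_cv2(acc20, "e1", 0.3, 5, 1), "2 environments")
})

test_that("leave-group-out builds one partition per group plus controls", {
  meta <- data.frame(accession = acc20,
                     group = rep(c("g1", "g2", "g3"), c(8, 7, 5)))
  part <- make_leave_group_out(meta, envs2, control_size = 6, n_controls = 10,
                               seed = 7)
  expect_equal(part$n_partitions, 13)
  expect_identical(part$labels[1:3], c("g1", "g2", "g3"))
  expect_equal(sum(part$masks[[1]][, 1]), 8)
  for (k in 4:13) expect_equal(sum(part$masks[[k]][, 1]), 6)
  # group partitions identical across calls regardless of seed
  part2 <- make_leave_group_out(meta, envs2, control_size = 6, seed = 99)
  expect_identical(part$masks[1:3], part2$masks[1:3])
  expect_error(make_leave_group_out(
    data.frame(accession = acc20, group = "all"), envs2), "full panel")
})

test_that("train and test cells partition the observed cells (no leakage)", {
  sim <- quick_dataset(n = 20, p = 30, seed = 8)
  sim$data$Y[1, 1] <- NA  # unbalanced incidence
  for (part in list(
      make_cv1(sim$data$accessions, sim$data$environments, 0.3, 4, 1),
      make_cv2(sim$data$accessions, sim$data$environments, 0.3, 4, 1))) {
    for (m in part$masks) {
      obs <- !is.na(sim$data$Y)
      train <- obs & !m
      test <- obs & m
      expect_true(all(xor(train, test) == obs))
      expect_false(any(train & test))
    }
  }
})

test_that("predictive ability equals the Pearson correlation", {
  v <- rnorm(10)
  expect_equal(predictive_ability(v, v), 1)
  expect_equal(predictive_ability(v, -v), -1)
  set.seed(9)
  a <- rnorm(30); b <- rnorm(30)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(predictive_ability(a, b), manual, tolerance = 1e-12)
  expect_warning(r <- predictive_ability(rep(1, 5), rnorm(5)), "zero variance")
  expect_true(is.na(r))
  expect_warning(r2 <- predictive_ability(rnorm(2), rnorm(2)), "fewer than 3")
  expect_true(is.na(r2))
})

test_that("bias slope is the regression of observed on GEBV", {
  g <- rnorm(15)
  expect_equal(prediction_bias(g, g), 1)
  expect_equal(prediction_bias(2 * g, g), 2)
  expect_error(prediction_bias(g, rep(1, 15)), "constant")
})

test_that("noise-free phenotypes are predicted almost perfectly", {
  # more training accessions than markers so the effects are identifiable
  X <- strip_mm(rand_marker_matrix(120, 30, seed = 10))
  set.seed(10)
  b <- rnorm(30, 0, sqrt(0.6 / 30))
  g <- drop(X$X %*% b)
  Y <- cbind(e1 = g, e2 = g)
  rownames(Y) <- rownames(X$X)
  dat <- multienv_dataset(Y, X)
  part <- make_cv1(dat$accessions, envs2, 0.3, 3, seed = 11)
  cv <- run_cv(dat, "across_env", part, fast_mcmc(800, 200, seed = 11))
  expect_true(all(cv$summary$mean_r > 0.95))
})

test_that("environments with too few test observations record missing r", {
  sim <- quick_dataset(n = 40, p = 30, seed = 12)
  acc <- sim$data$accessions
  # env2 observed for 14 accessions, 2 of which fall in the test set
  sim$data$Y[-(11:24), 2] <- NA
  mask <- matrix(FALSE, 40, 2, dimnames = list(acc, sim$data$environments))
  mask[1:12, ] <- TRUE
  part <- structure(list(scheme = "cv1", masks = list(mask),
                         accessions = acc,
                         environments = sim$data$environments,
                         test_fraction = 0.3, n_partitions = 1, seed = NA,
                         labels = "partition1"), class = "cv_partitions")
  expect_warning(cv <- run_cv(sim$data, "single_env", part,
                              fast_mcmc(400, 100, seed = 1)),
                 "fewer than 3 test")
  expect_true(any(is.na(cv$results$r)))
  expect_equal(cv$summary$n_used + cv$summary$n_missing, c(1, 1))
})

test_that("single-environment CV treats each environment independently", {
  sim <- quick_dataset(n = 60, p = 80, seed = 13)
  part <- make_cv1(sim$data$accessions, sim$data$environments, 0.3, 2,
                   seed = 13)
  cv <- run_cv(sim$data, "single_env", part, fast_mcmc(600, 150, seed = 2))
  expect_equal(nrow(cv$results), 4)
  expect_true(all(is.finite(cv$results$r)))
})

test_that("a full-set marker level reproduces the plain CV run", {
  sim <- quick_dataset(n = 50, p = 60, seed = 14)
  part <- make_cv1(sim$data$accessions, sim$data$environments, 0.3, 2,
                   seed = 14)
  st <- fast_mcmc(500, 100, seed = 3)
  plain <- run_cv(sim$data, "mxe", part, st)
  sweep1 <- marker_sweep(sim$data, "mxe", c(60, 20), part, st, seed = 4)
  expect_equal(sweep1[["60"]]$results$r, plain$results$r, tolerance = 1e-12)
  # subset draws reproducible under the same seed
  sweep2 <- marker_sweep(sim$data, "mxe", c(60, 20), part, st, seed = 4)
  expect_identical(sweep1[["20"]]$results, sweep2[["20"]]$results)
  expect_warning(marker_sweep(sim$data, "mxe", c(5), part, st, 1),
                 "below 10")
})

test_that("training-fraction sweep runs each requested fraction", {
  sim <- quick_dataset(n = 50, p = 60, seed = 15)
  st <- fast_mcmc(500, 100, seed = 5)
  sw <- training_fraction_sweep(sim$data, "across_env",
                                fractions = c(0.3, 0.6), n_partitions = 2,
                                settings = st, seed = 6)
  expect_identical(names(sw), c("0.3", "0.6"))
  expect_equal(nrow(attr(sw, "summary")), 4)
  # the default-fraction entry equals a plain run with the same partitions
  part <- make_cv1(sim$data$accessions, sim$data$environments, 0.3, 2,
                   seed = 6)
  plain <- run_cv(sim$data, "across_env", part, st)
  expect_equal(sw[["0.3"]]$results$r, plain$results$r, tolerance = 1e-12)
})

test_that("cross-population prediction is near-perfect on its own
          noise-free training set", {
  X <- strip_mm(rand_marker_matrix(80, 100, seed = 16))
  set.seed(16)
  b <- rnorm(100, 0, sqrt(0.6 / 100))
  g <- drop(X$X %*% b)
  Y <- cbind(e1 = g, e2 = g)
  rownames(Y) <- rownames(X$X)
  dat <- multienv_dataset(Y, X)
  res <- cross_population_predict(dat, X,
                                  matrix(g, ncol = 1,
                                         dimnames = list(rownames(X$X),
                                                         "new_env")),
                                  model = "across_env",
                                  settings = fast_mcmc(800, 200, seed = 7))
  expect_gt(res$pa$r, 0.95)
  expect_equal(length(res$overlap), 80)
  # phenotype-correlation report matches direct Pearson computation
  expect_equal(res$pheno_cor["e1", "new_env"], cor(Y[, "e1"], g),
               tolerance = 1e-12)
})

test_that("excluding the externally tested accessions lowers predictive
          ability on structured data", {
  deltas <- vapply(1:3, function(s) {
    sim <- simulate_allele_frequencies(
      sim_config(n_accessions = 90, n_markers = 250,
                 groups = c(a = 30, b = 30, c = 30), fst = 0.15,
                 pool_size = 60, seed = 30 + s))
    X <- standardise_markers(impute_missing(
      filter_markers(sim$panel, min_informative = 5)))
    cfg <- sim_config(n_accessions = 90, n_markers = X$p,
                      groups = c(all = 90), fst = 0, sigma2_u0 = 0.5,
                      sigma2_uj = c(0.1, 0.1), sigma2_e = 0.3,
                      seed = 30 + s)
    ph <- simulate_group_structured_effects(X, cfg, sim$groups,
                                            group_effect_sd = 0.6)
    test_acc <- rownames(X$X)[seq(1, 90, by = 3)]
    test_Y <- ph$data$Y[test_acc, 1, drop = FALSE]
    colnames(test_Y) <- "ext"
    st <- fast_mcmc(700, 150, seed = s)
    full <- cross_population_predict(ph$data, NULL, test_Y,
                                     model = "across_env", settings = st)
    excl <- cross_population_predict(ph$data, NULL, test_Y,
                                     model = "across_env", settings = st,
                                     exclude = test_acc)
    full$pa$r - excl$pa$r
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})
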