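## Cross-validation machinery: CV1 (test accessions unobserved everywhere),
## CV2 (test accessions masked in some environments, observed in the rest),
## leave-group-out hold-outs with random-removal controls, predictive
## ability and bias metrics, marker-number and training-fraction sweeps,
## and cross-population validation.

.new_partitions <- function(scheme, masks, accessions, environments,
                            test_fraction = NA, n_partitions = length(masks),
                            seed = NA, labels = NULL) {
  structure(list(scheme = scheme, masks = masks, accessions = accessions,
                 environments = environments, test_fraction = test_fraction,
                 n_partitions = n_partitions, seed = seed,
                 labels = labels %||% paste0("partition", seq_along(masks))),
            class = "cv_partitions")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cv_partitions <- function(x, ...) {
  cat("CV partitions (", x$scheme, "): ", x$n_partitions, " partitions, ",
      length(x$accessions), " accessions x ", length(x$environments),
      " environments\n", sep = "")
  invisible(x)
}

#' CV1 partitions: test accessions unobserved in every environment
#'
#' Each partition samples `floor(test_fraction * n)` accessions without
#' replacement and marks them as test in all environments.
#'
#' @param accessions accession ids.
#' @param environments environment labels.
#' @param test_fraction fraction of accessions held out (default 0.3, the
#'   70/30 split).
#' @param n_partitions number of random partitions (default 50).
#' @param seed RNG seed.
#' @return A `"cv_partitions"` object whose `masks` are per-partition
#'   accession-by-environment logical matrices (`TRUE` = test).
#' @export
make_cv1 <- function(accessions, environments, test_fraction = 0.3,
                     n_partitions = 50, seed = 1) {
  n <- length(accessions)
  n_test <- floor(test_fraction * n)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  if (n_test < 1) stop("test set is empty at this fraction")
  if (n - n_test < 2) stop("training set smaller than 2 accessions")
  set.seed(seed)
  masks <- lapply(seq_len(n_partitions), function(i) {
    test <- sample(n, n_test)
    m <- matrix(FALSE, n, length(environments),
                dimnames = list(accessions, environments))
    m[test, ] <- TRUE
    m
  })
  .new_partitions("cv1", masks, accessions, environments, test_fraction,
                  n_partitions, seed)
}

#' CV2 partitions: disjoint test sets, one per environment
#'
#' Per partition, `n_env` disjoint accession subsets of size
#' `floor(test_fraction * n)` are drawn; subset e is masked in environment
#' e only, so every test accession stays observed in the remaining
#' environments and the test sets do not overlap.
#'
#' @inheritParams make_cv1
#' @export
make_cv2 <- function(accessions, environments, test_fraction = 0.3,
                     n_partitions = 50, seed = 1) {
  n <- length(accessions)
  n_env <- length(environments)
  if (n_env < 2) stop("CV2 needs at least 2 environments")
  n_test <- floor(test_fraction * n)
  if (n_test < 1) stop("test set is empty at this fraction")
  if (n_test * n_env > n)
    stop("infeasible test_fraction: disjoint subsets need fraction <= ",
         round(1 / n_env, 3))
  set.seed(seed)
  masks <- lapply(seq_len(n_partitions), function(i) {
    picked <- sample(n, n_test * n_env)
    m <- matrix(FALSE, n, n_env, dimnames = list(accessions, environments))
    for (j in seq_len(n_env))
      m[picked[((j - 1) * n_test + 1):(j * n_test)], j] <- TRUE
    m
  })
  .new_partitions("cv2", masks, accessions, environments, test_fraction,
                  n_partitions, seed)
}

#' Leave-group-out partitions with random-removal controls
#'
#' One deterministic partition per group (all its accessions test in every
#' environment, CV1-style), plus `n_controls` random partitions each
#' removing `control_size` accessions, for gauging how much of the
#' leave-group-out drop is due to set size alone.
#'
#' @param metadata data frame with columns `accession` and `group` (region
#'   or breeders'-material label).
#' @param environments environment labels.
#' @param control_size accessions removed per random control; defaults to
#'   the largest group size.
#' @param n_controls number of random-control partitions (default 10).
#' @param seed RNG seed (controls only; group partitions are
#'   deterministic).
#' @export
make_leave_group_out <- function(metadata, environments, control_size = NULL,
                                 n_controls = 10, seed = 1) {
  stopifnot(all(c("accession", "group") %in% names(metadata)))
  if (any(is.na(metadata$group) | metadata$group == ""))
    stop("empty group labels")
  accessions <- as.character(metadata$accession)
  groups <- split(accessions, metadata$group)
  n <- length(accessions)
  if (any(lengths(groups) == n))
    stop("a group spans the full panel; nothing would remain for training")
  if (is.null(control_size)) control_size <- max(lengths(groups))
  mk <- function(test) {
    m <- matrix(FALSE, n, length(environments),
                dimnames = list(accessions, environments))
    m[test, ] <- TRUE
    m
  }
  group_masks <- lapply(groups, mk)
  set.seed(seed)
  ctrl_masks <- lapply(seq_len(n_controls),
                       function(i) mk(sample(accessions, control_size)))
  .new_partitions("leave_group_out", c(group_masks, ctrl_masks),
                  accessions, environments, NA,
                  length(group_masks) + n_controls, seed,
                  labels = c(names(groups),
                             paste0("control", seq_len(n_controls))))
}

#' Predictive ability: Pearson correlation of predicted and observed
#'
#' @param predicted,observed equal-length numeric vectors (length >= 3).
#' @return Pearson correlation, or `NA` with a warning when either vector
#'   has zero variance.
#' @export
predictive_ability <- function(predicted, observed) {
  ok <- is.finite(predicted) & is.finite(observed)
  predicted <- predicted[ok]; observed <- observed[ok]
  if (length(observed) < 3) {
    warning("fewer than 3 complete pairs; predictive ability undefined")
    return(NA_real_)
  }
  if (stats::sd(predicted) < .Machine$double.eps * 100 ||
      stats::sd(observed) < .Machine$double.eps * 100) {
    warning("zero variance; predictive ability undefined")
    return(NA_real_)
  }
  stats::cor(predicted, observed)
}

#' Prediction bias as the slope of observed on GEBV
#'
#' OLS slope of the observed phenotypes on the predicted genetic values;
#' a slope of 1 indicates no bias, larger deviations larger bias.
#'
#' @param observed observed phenotypes.
#' @param gebv predicted genetic values.
#' @return The regression slope.
#' @export
prediction_bias <- function(observed, gebv) {
  ok <- is.finite(observed) & is.finite(gebv)
  observed <- observed[ok]; gebv <- gebv[ok]
  if (length(observed) < 3) stop("need at least 3 observations")
  sxx <- sum((gebv - mean(gebv))^2)
  if (sxx < .Machine$double.eps * 100) stop("constant GEBVs; slope undefined")
  sum((gebv - mean(gebv)) * (observed - mean(observed))) / sxx
}

## fit the requested model on a masked copy of the data and return the
## full accession-by-environment prediction matrix
.fit_and_predict <- function(data, model, train_Y, settings) {
  if (model == "single_env") {
    pred <- matrix(NA_real_, nrow(data$Y), ncol(data$Y),
                   dimnames = dimnames(data$Y))
    for (j in seq_len(ncol(train_Y))) {
      yj <- train_Y[, j]
      yj <- yj[!is.na(yj)]
      fit <- fit_single_env(yj, data$X, settings)
      pred[, j] <- predict(fit)[data$accessions, 1]
    }
    pred
  } else {
    train <- multienv_dataset(train_Y, data$X)
    fit <- fit_gp(train, model = model, settings = settings)
    predict(fit)[data$accessions, , drop = FALSE]
  }
}

#' Run cross-validated genomic prediction
#'
#' For every partition the test cells are masked, the model is refitted on
#' the remaining cells, masked cells are predicted as
#' `mu_j + x'(b0 + b_j)`, and the per-environment Pearson correlation
#' between prediction and the held-out (scaled, normalised) phenotype is
#' recorded, together with a pooled bias slope per partition.  For the
#' single-environment model each environment is fitted separately, and the
#' CV1/CV2 distinction is immaterial (both are random hold-outs).
#'
#' @param data a `"multienv_data"`.
#' @param model `"single_env"`, `"across_env"` or `"mxe"`.
#' @param partitions a `"cv_partitions"` over the same accessions and
#'   environments.
#' @param settings an [mcmc_settings()].
#' @return A `"cv_result"`: `results` (long data frame: partition,
#'   environment, r, n_test), `bias` (per-partition pooled slope),
#'   `summary` (per-environment mean/sd over partitions with non-missing
#'   r), and metadata.
#' @export
run_cv <- function(data, model = c("mxe", "across_env", "single_env"),
                   partitions, settings = mcmc_settings()) {
  model <- match.arg(model)
  stopifnot(inherits(data, "multienv_data"),
            inherits(partitions, "cv_partitions"))
  if (!identical(sort(partitions$accessions), sort(data$accessions)))
    stop("partition accessions do not match the dataset")
  if (!identical(sort(partitions$environments), sort(data$environments)))
    stop("partition environments do not match the dataset")
  envs <- data$environments
  rows <- list(); bias <- numeric(0)
  for (k in seq_along(partitions$masks)) {
    mask <- partitions$masks[[k]][data$accessions, envs, drop = FALSE]
    train_Y <- data$Y
    train_Y[mask] <- NA
    pred <- .fit_and_predict(data, model, train_Y, settings)
    po <- pc <- numeric(0)
    for (j in seq_along(envs)) {
      test <- mask[, j] & !is.na(data$Y[, j])
      if (sum(test) < 3) {
        warning("partition ", partitions$labels[k], ", environment ",
                envs[j], ": fewer than 3 test observations; r recorded missing")
        r <- NA_real_
      } else {
        r <- suppressWarnings(
          predictive_ability(pred[test, j], data$Y[test, j]))
        po <- c(po, data$Y[test, j]); pc <- c(pc, pred[test, j])
      }
      rows[[length(rows) + 1]] <-
        data.frame(partition = partitions$labels[k], environment = envs[j],
                   r = r, n_test = sum(test))
    }
    bias[k] <- if (length(po) >= 3 &&
                   stats::sd(pc) > .Machine$double.eps * 100)
      prediction_bias(po, pc) else NA_real_
  }
  res <- do.call(rbind, rows)
  ok <- !is.na(res$r)
  summ <- do.call(rbind, lapply(envs, function(e) {
    ri <- res$r[ok & res$environment == e]
    data.frame(environment = e, mean_r = mean(ri), sd_r = stats::sd(ri),
               n_used = length(ri), n_missing = sum(res$environment == e) -
                 length(ri))
  }))
  structure(list(results = res, bias = bias, summary = summ,
                 model = model, scheme = partitions$scheme,
                 n_partitions = partitions$n_partitions,
                 n_markers = data$X$p,
                 test_fraction = partitions$test_fraction),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validation (", x$model, " model, ", x$scheme, " scheme, ",
      x$n_partitions, " partitions, ", x$n_markers, " markers)\n", sep = "")
  print(cbind(x$summary["environment"], round(x$summary[-1], 3)))
  if (any(!is.na(x$bias)))
    cat("  mean bias slope:", round(mean(x$bias, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Predictive ability across marker-subset sizes
#'
#' Re-runs cross-validation on random marker subsets of decreasing size
#' (the genomic relationship is rebuilt from each subset, since the fit
#' standardises per subset and divides by its own marker count).
#'
#' @param data a `"multienv_data"`.
#' @param model model name as in [run_cv()].
#' @param levels vector of marker counts to test.
#' @param partitions a `"cv_partitions"`.
#' @param settings an [mcmc_settings()].
#' @param seed RNG seed for the subset draws.
#' @return A list of `"cv_result"`s (one per level, named by level) with a
#'   `summary` data frame attribute across levels.
#' @export
marker_sweep <- function(data, model, levels, partitions,
                         settings = mcmc_settings(), seed = 1) {
  stopifnot(all(levels <= data$X$p))
  if (any(levels < 10)) warning("marker levels below 10 are unreliable")
  set.seed(seed)
  subsets <- lapply(levels, function(l) sort(sample(data$X$p, l)))
  out <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    sel <- subsets[[i]]
    Xs <- structure(list(X = data$X$X[, sel, drop = FALSE],
                         center = data$X$center[sel],
                         scale = data$X$scale[sel], p = length(sel)),
                    class = "marker_matrix")
    ds <- multienv_dataset(data$Y, Xs)
    out[[i]] <- run_cv(ds, model, partitions, settings)
  }
  names(out) <- as.character(levels)
  attr(out, "summary") <- do.call(rbind, lapply(seq_along(out), function(i)
    cbind(n_markers = levels[i], out[[i]]$summary)))
  out
}

#' Predictive ability across training-set sizes
#'
#' Runs CV1-style cross-validation at a series of test-set fractions.
#'
#' @param data a `"multienv_data"`.
#' @param model model name as in [run_cv()].
#' @param fractions test-set fractions (default 0.3 to 0.9 by 0.1).
#' @param n_partitions partitions per fraction (default 50).
#' @param settings an [mcmc_settings()].
#' @param seed partition seed.
#' @return A list of `"cv_result"`s named by fraction, with a cross-level
#'   `summary` attribute.
#' @export
training_fraction_sweep <- function(data, model,
                                    fractions = seq(0.3, 0.9, by = 0.1),
                                    n_partitions = 50,
                                    settings = mcmc_settings(), seed = 1) {
  stopifnot(all(fractions > 0 & fractions < 1))
  out <- vector("list", length(fractions))
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    n_train <- length(data$accessions) - floor(f * length(data$accessions))
    if (n_train < 10)
      warning("training set of ", n_train, " accessions at test fraction ",
              f, " is very small")
    part <- make_cv1(data$accessions, data$environments, test_fraction = f,
                     n_partitions = n_partitions, seed = seed)
    out[[i]] <- run_cv(data, model, part, settings)
  }
  names(out) <- as.character(fractions)
  attr(out, "summary") <- do.call(rbind, lapply(seq_along(out), function(i)
    cbind(test_fraction = fractions[i], out[[i]]$summary)))
  out
}

#' Cross-population validation on new phenotypic data
#'
#' Fits the model on the full training dataset and correlates projected
#' GEBVs with phenotypes collected on (possibly overlapping) accessions in
#' new environments.  Held-out genotypes are standardised with the
#' training means and sds.  An `exclude` list emulates training variants
#' with the externally tested accessions removed.
#'
#' @param train a `"multienv_data"` (training population).
#' @param test_genotypes an imputed `"freq_panel"` (or `"marker_matrix"`
#'   already on the training scale) for the test accessions.
#' @param test_phenotypes accession-by-environment matrix (or data frame)
#'   of test-population BLUEs, row names = accessions.
#' @param model model name as in [run_cv()].
#' @param settings an [mcmc_settings()].
#' @param exclude accession ids removed from training before the fit.
#' @return A `"cross_pop_result"`: `pa` (per test environment: r, n), the
#'   main-effect `gebv` used, `overlap` (test accessions also in
#'   training), and `pheno_cor` (training-by-test environment phenotype
#'   correlations over shared accessions).
#' @export
cross_population_predict <- function(train, test_genotypes, test_phenotypes,
                                     model = c("mxe", "across_env",
                                               "single_env"),
                                     settings = mcmc_settings(),
                                     exclude = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(train, "multienv_data"))
  test_Y <- as.matrix(test_phenotypes)
  if (is.null(rownames(test_Y))) stop("test phenotypes need accession names")

  if (is.null(test_genotypes)) {
    testX <- train$X$X  # test accessions genotyped within the training panel
  } else if (inherits(test_genotypes, "freq_panel")) {
    shared_mk <- intersect(colnames(test_genotypes$freqs),
                           colnames(train$X$X))
    if (length(shared_mk) == 0)
      stop("no marker overlap between training and test genotypes")
    if (length(shared_mk) < ncol(train$X$X))
      stop("test panel lacks ", ncol(train$X$X) - length(shared_mk),
           " training markers; subset the training panel first")
    sub <- freq_panel(test_genotypes$freqs[, colnames(train$X$X),
                                           drop = FALSE], "raw")
    sub$qc_state <- "imputed"
    testX <- standardise_markers(sub, center = train$X$center,
                                 scale = train$X$scale)$X
  } else if (inherits(test_genotypes, "marker_matrix")) {
    testX <- test_genotypes$X
  } else testX <- as.matrix(test_genotypes)

  train_Y <- train$Y
  if (!is.null(exclude)) {
    keep <- !(rownames(train_Y) %in% exclude)
    train_Y <- train_Y[keep, , drop = FALSE]
  }
  sub_train <- multienv_dataset(
    train_Y,
    structure(list(X = train$X$X[rownames(train_Y), , drop = FALSE],
                   center = train$X$center, scale = train$X$scale,
                   p = train$X$p), class = "marker_matrix"))
  if (ncol(train_Y) == 1) model <- "single_env"
  fit <- fit_gp(sub_train, model = model, settings = settings)

  gebv <- drop(testX %*% fit$b0)  # main genetic value: new environments
  names(gebv) <- rownames(testX)
  shared <- intersect(rownames(test_Y), names(gebv))
  if (length(shared) == 0) stop("no test accession has genotype data")
  pa <- do.call(rbind, lapply(colnames(test_Y), function(e) {
    yv <- test_Y[shared, e]
    data.frame(test_env = e,
               r = suppressWarnings(predictive_ability(gebv[shared], yv)),
               n = sum(is.finite(yv)))
  }))

  shared_tr <- intersect(rownames(train$Y), rownames(test_Y))
  pheno_cor <- matrix(NA_real_, ncol(train$Y), ncol(test_Y),
                      dimnames = list(colnames(train$Y), colnames(test_Y)))
  if (length(shared_tr) >= 3)
    for (a in colnames(train$Y)) for (b in colnames(test_Y)) {
      pair <- cbind(train$Y[shared_tr, a], test_Y[shared_tr, b])
      pair <- pair[stats::complete.cases(pair), , drop = FALSE]
      if (nrow(pair) >= 3) pheno_cor[a, b] <- stats::cor(pair[, 1], pair[, 2])
    }

  structure(list(pa = pa, gebv = gebv,
                 overlap = intersect(rownames(test_Y), rownames(train_Y)),
                 excluded = exclude, pheno_cor = pheno_cor, model = model),
            class = "cross_pop_result")
}

#' @export
print.cross_pop_result <- function(x, ...) {
  cat("Cross-population validation (", x$model, " model)\n", sep = "")
  print(cbind(x$pa["test_env"], round(x$pa[-1], 3)))
  cat("  overlap with training set:", length(x$overlap), "accessions\n")
  invisible(x)
}
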