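## Genomic-prediction models.  Three GBLUP strategies over standardised
## allele-frequency markers:
##
##   SingleEnv  y_j = 1 mu_j + X beta_j + eps_j          (one env at a time)
##   AcrossEnv  shared marker effects b0 for all envs    (G0 kernel)
##   MxE        beta_jk = b_0k + b_jk: shared effects plus environment-
##              specific deviations (G0 + block-diagonal G1 kernels)
##
## All are fitted by Gibbs sampling in marker-effect space (Bayesian ridge,
## one variance per effect block), which is equivalent to the G-matrix
## formulation with G = XX'/p because the marker matrix is identical across
## environments.  A closed-form multi-kernel GBLUP (gblup_oracle) provides
## the deterministic reference solution at fixed variance components.

#' Assemble a multi-environment phenotype dataset
#'
#' @param Y accession-by-environment matrix of (scaled, normalised) BLUEs;
#'   `NA` marks accession-environment cells without observations.  Row
#'   names must match the rows of `X`.
#' @param X a `"marker_matrix"` from [standardise_markers()] covering every
#'   accession in `Y`.
#' @return A `"multienv_data"` list with `Y`, `X`, `accessions`,
#'   `environments`.
#' @export
multienv_dataset <- function(Y, X) {
  stopifnot(inherits(X, "marker_matrix"))
  Y <- as.matrix(Y)
  if (is.null(rownames(Y))) stop("Y must carry accession row names")
  if (is.null(colnames(Y)))
    colnames(Y) <- paste0("env", seq_len(ncol(Y)))
  missing_acc <- setdiff(rownames(Y), rownames(X$X))
  if (length(missing_acc) > 0)
    stop("accessions absent from the marker matrix: ",
         paste(utils::head(missing_acc, 5), collapse = ", "))
  empty <- colSums(!is.na(Y)) == 0
  if (any(empty))
    stop("environment(s) with no observed accessions: ",
         paste(colnames(Y)[empty], collapse = ", "))
  structure(list(Y = Y, X = X, accessions = rownames(Y),
                 environments = colnames(Y)),
            class = "multienv_data")
}

#' @export
print.multienv_data <- function(x, ...) {
  cat("Multi-environment dataset:", nrow(x$Y), "accessions x",
      ncol(x$Y), "environments,", x$X$p, "markers\n")
  cat("  observed cells:", sum(!is.na(x$Y)), "of", length(x$Y), "\n")
  invisible(x)
}

#' MCMC settings for the Gibbs sampler
#'
#' @param n_iter total Gibbs iterations (default 25000).
#' @param burn_in discarded initial iterations (default 2500).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed optional RNG seed applied at the start of each fit.
#' @param prior_df degrees of freedom of the scaled-inverse-chi-square
#'   priors on all variance components.
#' @param prior_R2 prior proportion of the phenotypic variance allocated
#'   (equally) to the genetic effect blocks; the rest goes to the residual.
#' @return An `"mcmc_settings"` list.
#' @export
mcmc_settings <- function(n_iter = 25000, burn_in = 2500, thin = 5,
                          seed = NULL, prior_df = 5, prior_R2 = 0.5) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (prior_R2 <= 0 || prior_R2 >= 1) stop("prior_R2 must be in (0, 1)")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed,
                 prior_df = prior_df, prior_R2 = prior_R2),
            class = "mcmc_settings")
}

#' Variance components of a genomic-prediction model
#'
#' Container for the main genetic variance, the per-environment specific
#' variances (MxE only) and the residual variance, used both for reporting
#' posterior means and for fixing components in [gblup_oracle()].
#'
#' @param sigma2_u0 main (across-environment) genetic variance.
#' @param sigma2_uj named vector of environment-specific variances (MxE
#'   model), or `NULL`.
#' @param sigma2_e residual variance.
#' @param model `"single_env"`, `"across_env"` or `"mxe"`.
#' @return A `"variance_components"` list.
#' @export
variance_components <- function(sigma2_u0, sigma2_uj = NULL, sigma2_e,
                                model = c("single_env", "across_env", "mxe")) {
  model <- match.arg(model)
  if (sigma2_u0 < 0 || sigma2_e < 0 || any(sigma2_uj < 0))
    stop("variance components must be non-negative")
  if (model != "mxe" && !is.null(sigma2_uj))
    stop("sigma2_uj applies only to the mxe model")
  if (model == "mxe" && is.null(sigma2_uj))
    stop("the mxe model requires sigma2_uj")
  structure(list(sigma2_u0 = sigma2_u0, sigma2_uj = sigma2_uj,
                 sigma2_e = sigma2_e, model = model),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (", x$model, " model)\n", sep = "")
  cat("  main genetic  :", signif(x$sigma2_u0, 4), "\n")
  if (!is.null(x$sigma2_uj)) {
    cat("  env-specific  :\n")
    print(signif(x$sigma2_uj, 4))
  }
  cat("  residual      :", signif(x$sigma2_e, 4), "\n")
  invisible(x)
}

#' Per-environment variance-explained decomposition
#'
#' Computes, for each environment j,
#' \deqn{R^2_j = (\sigma^2_{u0} + \sigma^2_{uj}) /
#'       (\sigma^2_\epsilon + \sigma^2_{u0} + \sigma^2_{uj})}
#' (the environment-specific term is absent for the single- and
#' across-environment models), along with the fractions of total variance
#' attributed to main, specific and residual sources.
#'
#' @param vc a `"variance_components"` object or a fitted `"gpfit"` (whose
#'   posterior-mean components are used).
#' @return A data frame with columns `environment`, `r2`, `frac_main`,
#'   `frac_specific`, `frac_residual`.
#' @export
variance_r2 <- function(vc) {
  if (inherits(vc, "gpfit")) vc <- vc$varcomps
  stopifnot(inherits(vc, "variance_components"))
  uj <- if (is.null(vc$sigma2_uj)) 0 else vc$sigma2_uj
  tot <- vc$sigma2_u0 + uj + vc$sigma2_e
  if (all(tot == 0)) stop("all variance components are zero")
  envs <- if (is.null(vc$sigma2_uj) || is.null(names(vc$sigma2_uj)))
    paste0("env", seq_along(tot)) else names(vc$sigma2_uj)
  data.frame(environment = envs,
             r2 = (vc$sigma2_u0 + uj) / tot,
             frac_main = vc$sigma2_u0 / tot,
             frac_specific = uj / tot,
             frac_residual = vc$sigma2_e / tot,
             row.names = NULL)
}

## ---- Gibbs fitting -------------------------------------------------------

#' Fit a genomic-prediction model by Gibbs sampling
#'
#' Fits one of the three GBLUP strategies to a multi-environment dataset by
#' Gibbs sampling of the equivalent marker-effect (Bayesian ridge)
#' parameterisation, with a shared effect block (`across_env`, `mxe`) and
#' one block per environment (`mxe` only).  Variance components carry
#' scaled-inverse-chi-square priors whose scales allocate `prior_R2` of
#' the phenotypic variance to the genetic blocks; intercepts are flat.
#'
#' @param data a `"multienv_data"`.
#' @param model `"single_env"` (requires exactly one environment),
#'   `"across_env"` or `"mxe"` (require at least two).
#' @param settings an [mcmc_settings()].
#' @param fixed_varcomps optional `"variance_components"`; when given, the
#'   variance components are held fixed and only effects are sampled
#'   (used for oracle comparisons).
#' @param per_env_residual reserved flag; only the common-residual model is
#'   currently sampled.
#' @return A `"gpfit"` object; see Details.
#' @details The returned object contains posterior means of the
#'   per-environment intercepts `mu`, shared marker effects `b0` and main
#'   GEBVs `u0 = X b0`, environment-specific effects `bj` and GEBVs
#'   `u1 = X bj` (MxE only), posterior-mean `varcomps`, a per-environment
#'   `r2` table (posterior mean of the per-draw ratio), and the retained
#'   draws of intercepts and variance components in `samples`.
#' @export
fit_gp <- function(data, model = c("mxe", "across_env", "single_env"),
                   settings = mcmc_settings(), fixed_varcomps = NULL,
                   per_env_residual = FALSE) {
  stopifnot(inherits(data, "multienv_data"), inherits(settings, "mcmc_settings"))
  model <- match.arg(model)
  if (per_env_residual)
    stop("per-environment residual variances are not implemented; ",
         "the common-residual model matches the single epsilon term")
  n_env <- ncol(data$Y)
  if (model == "single_env" && n_env != 1)
    stop("single_env expects exactly one environment; use across_env/mxe")
  if (model != "single_env" && n_env < 2)
    stop("multi-environment models need at least 2 environments; ",
         "use fit_single_env for one")

  obs <- which(!is.na(data$Y), arr.ind = TRUE)
  y <- data$Y[obs]
  if (length(y) < 10)
    stop("fewer than 10 observations; posterior would be prior-dominated")
  if (any(!is.finite(y))) stop("non-finite phenotypes")
  acc0 <- match(rownames(data$Y)[obs[, 1]], rownames(data$X$X)) - 1L
  env0 <- obs[, 2] - 1L
  p <- data$X$p
  env_specific <- model == "mxe"
  n_kern <- if (env_specific) 1L + n_env else 1L

  vy <- max(stats::var(y), 1e-8)  # floor keeps degenerate inputs proper
  df0 <- settings$prior_df
  dfe <- settings$prior_df
  if (is.null(fixed_varcomps)) {
    target_u <- settings$prior_R2 * vy / n_kern
    S0b <- rep((target_u / p) * (df0 + 2) / df0, n_kern)
    S0e <- (1 - settings$prior_R2) * vy * (dfe + 2) / dfe
    init_s2b <- rep(target_u / p, n_kern)
    init_s2e <- (1 - settings$prior_R2) * vy
    fix_var <- FALSE
  } else {
    stopifnot(inherits(fixed_varcomps, "variance_components"))
    init_s2b <- fixed_varcomps$sigma2_u0 / p
    if (env_specific) {
      uj <- fixed_varcomps$sigma2_uj
      if (length(uj) == 1) uj <- rep(uj, n_env)
      init_s2b <- c(init_s2b, uj / p)
    }
    init_s2e <- fixed_varcomps$sigma2_e
    S0b <- init_s2b
    S0e <- init_s2e
    fix_var <- TRUE
  }

  if (!is.null(settings$seed)) set.seed(settings$seed)
  res <- .gibbs_ridge(y, acc0, env0, data$X$X, n_env, env_specific,
                      settings$n_iter, settings$burn_in, settings$thin,
                      df0, S0b, dfe, S0e, fix_var, init_s2b, init_s2e)

  envs <- colnames(data$Y)
  s <- res$samples
  colnames(s) <- c(paste0("mu_", envs),
                   "sigma2_u0",
                   if (env_specific) paste0("sigma2_u_", envs),
                   "sigma2_e",
                   paste0("r2_", envs))

  b0 <- res$b_mean[, 1]
  names(b0) <- colnames(data$X$X)
  u0 <- drop(data$X$X %*% b0)
  names(u0) <- rownames(data$X$X)
  if (env_specific) {
    bj <- res$b_mean[, -1, drop = FALSE]
    dimnames(bj) <- list(colnames(data$X$X), envs)
    u1 <- data$X$X %*% bj
    rownames(u1) <- rownames(data$X$X)
  } else {
    bj <- NULL
    u1 <- NULL
  }

  uj_hat <- if (env_specific)
    stats::setNames(colMeans(s[, paste0("sigma2_u_", envs), drop = FALSE]),
                    envs) else NULL
  vc <- variance_components(sigma2_u0 = mean(s[, "sigma2_u0"]),
                            sigma2_uj = uj_hat,
                            sigma2_e = mean(s[, "sigma2_e"]),
                            model = model)
  r2 <- data.frame(environment = envs,
                   r2 = colMeans(s[, paste0("r2_", envs), drop = FALSE]),
                   r2_sd = apply(s[, paste0("r2_", envs), drop = FALSE], 2,
                                 stats::sd),
                   row.names = NULL)
  vc_sd <- apply(s[, grep("^sigma2", colnames(s)), drop = FALSE], 2,
                 stats::sd)

  structure(list(model = model,
                 mu = stats::setNames(res$mu_mean, envs),
                 b0 = b0, bj = bj, u0 = u0, u1 = u1,
                 varcomps = vc, varcomp_sd = vc_sd, r2 = r2,
                 samples = s, settings = settings,
                 accessions = rownames(data$X$X),
                 environments = envs,
                 data = data),
            class = "gpfit")
}

#' Fit the single-environment GBLUP model
#'
#' @param y named vector of (scaled, normalised) phenotypes, or a
#'   one-column matrix; names must match rows of `X`.
#' @param X a `"marker_matrix"`.
#' @param settings an [mcmc_settings()].
#' @param ... passed on to [fit_gp()].
#' @return A `"gpfit"` with `model = "single_env"`.
#' @export
fit_single_env <- function(y, X, settings = mcmc_settings(), ...) {
  if (is.matrix(y) && ncol(y) == 1) y <- stats::setNames(y[, 1], rownames(y))
  if (is.null(names(y))) stop("y must carry accession names")
  Y <- matrix(y, ncol = 1, dimnames = list(names(y), "env1"))
  fit_gp(multienv_dataset(Y, X), model = "single_env", settings = settings,
         ...)
}

#' Fit the across-environment GBLUP model (shared marker effects)
#'
#' @param data a `"multienv_data"` with at least two environments.
#' @inheritParams fit_single_env
#' @return A `"gpfit"` with `model = "across_env"`.
#' @export
fit_across_env <- function(data, settings = mcmc_settings(), ...) {
  fit_gp(data, model = "across_env", settings = settings, ...)
}

#' Fit the marker-by-environment interaction GBLUP model
#'
#' @inheritParams fit_across_env
#' @return A `"gpfit"` with `model = "mxe"`.
#' @export
fit_mxe <- function(data, settings = mcmc_settings(), ...) {
  fit_gp(data, model = "mxe", settings = settings, ...)
}

## ---- gpfit methods -------------------------------------------------------

#' @export
print.gpfit <- function(x, ...) {
  cat("Genomic-prediction fit (", x$model, " model)\n", sep = "")
  cat("  ", length(x$accessions), " accessions, ", x$data$X$p, " markers, ",
      length(x$environments), " environment(s)\n", sep = "")
  cat("  Gibbs: ", x$settings$n_iter, " iterations (burn-in ",
      x$settings$burn_in, ", thin ", x$settings$thin, ")\n", sep = "")
  print(x$varcomps)
  cat("  per-environment R2:\n")
  print(cbind(x$r2[, "environment", drop = FALSE],
              round(x$r2[, c("r2", "r2_sd")], 3)))
  invisible(x)
}

#' @export
summary.gpfit <- function(object, ...) {
  out <- list(model = object$model, varcomps = object$varcomps,
              varcomp_sd = object$varcomp_sd, r2 = object$r2,
              mu = object$mu, posterior = posterior_summary(object))
  class(out) <- "summary.gpfit"
  out
}

#' @export
print.summary.gpfit <- function(x, ...) {
  cat("Posterior summary (", x$model, " model)\n", sep = "")
  print(round(x$posterior, 4))
  invisible(x)
}

#' @export
coef.gpfit <- function(object, ...) {
  cbind(b0 = object$b0, object$bj)
}

#' Predict genetic values for accessions and environments
#'
#' Prediction for accession a in environment j is
#' `mu_j + x_a' (b0 + b_j)` (the `b_j` term only for the MxE model); this
#' is how masked accession-environment cells are predicted in
#' cross-validation.
#'
#' @param object a `"gpfit"`.
#' @param newdata optional `"marker_matrix"` (projected on the training
#'   standardisation) for accessions not in the fit; defaults to the
#'   training accessions.
#' @param what `"value"` (mu + GEBV, default) or `"gebv"` (genetic value
#'   only, u0 + u1).
#' @param ... unused.
#' @return Accession-by-environment matrix.
#' @export
predict.gpfit <- function(object, newdata = NULL,
                          what = c("value", "gebv"), ...) {
  what <- match.arg(what)
  X <- if (is.null(newdata)) object$data$X$X
       else if (inherits(newdata, "marker_matrix")) newdata$X
       else as.matrix(newdata)
  if (ncol(X) != length(object$b0))
    stop("newdata has ", ncol(X), " markers; fit used ", length(object$b0))
  u0 <- drop(X %*% object$b0)
  out <- matrix(u0, nrow = nrow(X), ncol = length(object$environments),
                dimnames = list(rownames(X), object$environments))
  if (!is.null(object$bj)) out <- out + X %*% object$bj
  if (what == "value") out <- sweep(out, 2, object$mu, "+")
  out
}

#' @export
fitted.gpfit <- function(object, ...) {
  pr <- predict(object)
  pr[is.na(object$data$Y)] <- NA
  pr
}

#' @export
residuals.gpfit <- function(object, ...) {
  object$data$Y - fitted(object)
}

#' Posterior summary table of a Gibbs fit
#'
#' @param fit a `"gpfit"` with retained draws.
#' @param prob credible-interval mass.
#' @return Matrix with posterior mean, sd, credible bounds and effective
#'   sample size per retained parameter (intercepts, variance components,
#'   per-environment R2).
#' @export
posterior_summary <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "gpfit"))
  s <- fit$samples
  if (is.null(s) || nrow(s) == 0) stop("fit has no retained samples")
  a <- (1 - prob) / 2
  t(apply(s, 2, function(x) {
    c(mean = mean(x), sd = stats::sd(x),
      lower = unname(stats::quantile(x, a)),
      upper = unname(stats::quantile(x, 1 - a)),
      ess = .ess(x))
  }))
}

## effective sample size by the initial-positive-sequence autocorrelation rule
.ess <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  neg <- which(rho < 0)
  if (length(neg) > 0) rho <- rho[seq_len(neg[1] - 1)]
  max(1, n / (1 + 2 * sum(rho)))
}

## ---- closed-form oracle --------------------------------------------------

#' Closed-form multi-kernel GBLUP at fixed variance components
#'
#' Exact mixed-model solution used as the deterministic reference for the
#' Gibbs fits: with observed cells stacked into y, kernels
#' \eqn{K_0 = Z G Z'} (shared) and, for the MxE model, per-environment
#' blocks \eqn{K_j}, the phenotypic covariance is
#' \eqn{V = \sigma^2_{u0} K_0 + \sum_j \sigma^2_{uj} K_j + \sigma^2_\epsilon I};
#' intercepts are estimated by GLS and each BLUP is
#' \eqn{\hat u_m = \sigma^2_m \mathrm{Cov}(u_m, y) V^{-1}(y - W\hat\mu)},
#' evaluated by dense linear algebra.
#'
#' @param data a `"multienv_data"` (a single-environment dataset gives the
#'   SingleEnv solution).
#' @param G a `"grm"` (or plain symmetric matrix) over the accessions of
#'   `data`, typically [compute_grm()] of its marker matrix.
#' @param varcomps a `"variance_components"`; its `model` field decides
#'   whether environment-specific kernels are used.
#' @return List with `mu` (GLS intercepts), `u0` (main GEBV per accession),
#'   `u1` (accession-by-environment specific GEBVs, MxE only), and
#'   `fitted` (accession-by-environment mu + GEBV matrix).
#' @export
gblup_oracle <- function(data, G, varcomps) {
  stopifnot(inherits(data, "multienv_data"),
            inherits(varcomps, "variance_components"))
  G <- unclass(G)[data$accessions, data$accessions]
  obs <- which(!is.na(data$Y), arr.ind = TRUE)
  y <- data$Y[obs]
  n <- length(y)
  n_env <- ncol(data$Y)
  a_idx <- obs[, 1]
  e_idx <- obs[, 2]

  K0 <- G[a_idx, a_idx]
  V <- varcomps$sigma2_u0 * K0
  use_specific <- varcomps$model == "mxe"
  if (use_specific) {
    uj <- varcomps$sigma2_uj
    if (length(uj) == 1) uj <- rep(uj, n_env)
    for (j in seq_len(n_env)) {
      sel <- e_idx == j
      V[sel, sel] <- V[sel, sel] + uj[j] * K0[sel, sel]
    }
  }
  diag(V) <- diag(V) + varcomps$sigma2_e
  W <- matrix(0, n, n_env)
  W[cbind(seq_len(n), e_idx)] <- 1
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular phenotypic covariance matrix V"))
  WtVi <- crossprod(W, Vi)
  mu <- solve(WtVi %*% W, WtVi %*% y)[, 1]
  names(mu) <- colnames(data$Y)
  alpha <- Vi %*% (y - W %*% mu)

  # accession-level BLUPs (including accessions with no observations)
  u0 <- varcomps$sigma2_u0 * drop(G[, a_idx] %*% alpha)
  names(u0) <- data$accessions
  u1 <- NULL
  if (use_specific) {
    u1 <- matrix(0, nrow(G), n_env,
                 dimnames = list(data$accessions, colnames(data$Y)))
    for (j in seq_len(n_env)) {
      sel <- e_idx == j
      if (any(sel))
        u1[, j] <- uj[j] * drop(G[, a_idx[sel], drop = FALSE] %*% alpha[sel])
    }
  }
  fit <- matrix(u0, nrow(G), n_env,
                dimnames = list(data$accessions, colnames(data$Y)))
  if (use_specific) fit <- fit + u1
  fit <- sweep(fit, 2, mu, "+")
  list(mu = mu, u0 = u0, u1 = u1, fitted = fit)
}
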