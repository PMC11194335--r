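# Small fixtures built in code.

# random raw panel with optional missingness
rand_panel <- function(n_acc = 10, n_mk = 8, missing = 0, seed = 1) {
  set.seed(seed)
  f <- matrix(runif(n_acc * n_mk), n_acc, n_mk,
              dimnames = list(sprintf("a%02d", seq_len(n_acc)),
                              sprintf("m%02d", seq_len(n_mk))))
  if (missing > 0) f[sample(length(f), missing)] <- NA
  freq_panel(f, "raw")
}

# standardised marker matrix straight from gaussian noise (bypasses the
# allele-frequency layer where only the GBLUP machinery is under test).
# The seed is offset so a caller reusing `seed` for marker effects or noise
# draws from a different stream than the one that generated X — otherwise
# the "noise" would literally be a column of X and the model could
# interpolate it.
rand_marker_matrix <- function(n = 50, p = 100, seed = 1,
                               ids = sprintf("a%03d", seq_len(n))) {
  set.seed(seed + 1000000L)
  M <- matrix(rnorm(n * p), n, p,
              dimnames = list(ids, sprintf("m%04d", seq_len(p))))
  M <- scale(M)
  structure(list(X = M, center = attr(M, "scaled:center"),
                 scale = attr(M, "scaled:scale"), p = p),
            class = "marker_matrix")
}

strip_mm <- function(mm) {
  mm$X <- matrix(as.numeric(mm$X), nrow(mm$X), ncol(mm$X),
                 dimnames = dimnames(mm$X))
  mm
}

# quick two-environment dataset simulated under the interaction model
quick_dataset <- function(n = 80, p = 120, s2u0 = 0.4, s2uj = 0.2,
                          s2e = 0.4, seed = 1, n_env = 2) {
  X <- strip_mm(rand_marker_matrix(n, p, seed))
  cfg <- sim_config(n_accessions = n, n_markers = p,
                    groups = c(g = n), fst = 0, pool_size = 100,
                    env_names = paste0("env", seq_len(n_env)),
                    sigma2_u0 = s2u0, sigma2_uj = rep(s2uj, n_env),
                    sigma2_e = s2e, seed = seed)
  simulate_multienv_phenotypes(X, cfg)
}

fast_mcmc <- function(n_iter = 1200, burn_in = 200, seed = 11, thin = 1)
  mcmc_settings(n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed)
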