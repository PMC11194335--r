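## Synthetic data generator.  Emulates the shape of a pool-GBS
## multi-environment trial panel: accession-level allele frequencies with
## regional population structure (Balding-Nichols differentiation and
## binomial pool sampling), multi-environment phenotypes under the
## shared-plus-environment-specific marker-effect model, and plot-level
## field layouts with block/row/column effects.

#' Configuration of a synthetic study
#'
#' Defaults mirror the panel the package is designed around: 392
#' pool-genotyped accessions and 20,156 SNP allele frequencies in five
#' regional groups, pools of 200 individuals, and two environments with
#' main genetic variance 0.4, environment-specific variance 0.2 and
#' residual variance 0.4 on the standardised-phenotype scale.
#'
#' @param n_accessions number of accessions.
#' @param n_markers number of SNP markers.
#' @param groups named integer vector of group sizes (regions or breeders'
#'   material) summing to `n_accessions`.
#' @param fst differentiation of group allele frequencies from the
#'   ancestral pool, in \[0, 1).
#' @param pool_size individuals per pooled DNA sample; accession
#'   frequencies are binomial proportions out of `2 * pool_size` draws.
#' @param missing_rate fraction of entries set missing at random.
#' @param env_names environment labels.
#' @param mu_env per-environment intercepts.
#' @param sigma2_u0 main (shared) genetic variance.
#' @param sigma2_uj per-environment specific genetic variances (recycled).
#' @param sigma2_e residual variance.
#' @param seed RNG seed.
#' @return A `"sim_config"` list.
#' @export
sim_config <- function(n_accessions = 392, n_markers = 20156,
                       groups = c(N_eur = 142, C_eur = 120, E_eur = 70,
                                  Amer = 44, CHE = 16),
                       fst = 0.1, pool_size = 200, missing_rate = 0,
                       env_names = c("env1", "env2"),
                       mu_env = rep(0, length(env_names)),
                       sigma2_u0 = 0.4,
                       sigma2_uj = rep(0.2, length(env_names)),
                       sigma2_e = 0.4, seed = 1) {
  # tolerate YAML round trips, which deliver vectors as lists
  groups <- unlist(groups)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  env_names <- unlist(env_names)
  mu_env <- unlist(mu_env)
  sigma2_uj <- unlist(sigma2_uj)
  if (sum(groups) != n_accessions)
    stop("group sizes must sum to n_accessions")
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  if (sigma2_u0 < 0 || sigma2_e < 0 || any(sigma2_uj < 0))
    stop("variances must be non-negative")
  sigma2_uj <- rep_len(sigma2_uj, length(env_names))
  mu_env <- rep_len(mu_env, length(env_names))
  structure(list(n_accessions = n_accessions, n_markers = n_markers,
                 groups = groups, fst = fst, pool_size = pool_size,
                 missing_rate = missing_rate, env_names = env_names,
                 mu_env = mu_env, sigma2_u0 = sigma2_u0,
                 sigma2_uj = sigma2_uj, sigma2_e = sigma2_e, seed = seed),
            class = "sim_config")
}

#' Simulate a structured allele-frequency panel
#'
#' Ancestral frequencies are uniform on \[0.1, 0.9\]; each group draws its
#' frequencies from the Balding-Nichols beta distribution with parameter
#' `fst`; each accession's observed frequency is a binomial pool-sampling
#' proportion out of `2 * pool_size` draws, which folds pool-sampling and
#' sequencing noise into a single binomial layer.
#'
#' @param cfg a [sim_config()].
#' @return List with `panel` (a raw `"freq_panel"`) and `groups` (named
#'   character vector of group labels per accession).
#' @export
simulate_allele_frequencies <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  p <- cfg$n_markers
  anc <- stats::runif(p, 0.1, 0.9)
  group_of <- rep(names(cfg$groups), cfg$groups)
  freqs <- matrix(NA_real_, cfg$n_accessions, p,
                  dimnames = list(sprintf("acc%03d", seq_len(cfg$n_accessions)),
                                  sprintf("mk%05d", seq_len(p))))
  n2 <- 2 * cfg$pool_size
  for (g in names(cfg$groups)) {
    pg <- if (cfg$fst == 0) anc else
      stats::rbeta(p, anc * (1 - cfg$fst) / cfg$fst,
                   (1 - anc) * (1 - cfg$fst) / cfg$fst)
    rows <- which(group_of == g)
    draws <- matrix(stats::rbinom(length(rows) * p, n2, rep(pg, each =
                                                              length(rows))),
                    length(rows), p)
    freqs[rows, ] <- draws / n2
  }
  if (cfg$missing_rate > 0) {
    nmiss <- round(cfg$missing_rate * length(freqs))
    freqs[sample(length(freqs), nmiss)] <- NA
  }
  list(panel = freq_panel(freqs, "raw"),
       groups = stats::setNames(group_of, rownames(freqs)))
}

#' Simulate multi-environment phenotypes under the MxE generative model
#'
#' Marker effects split into a shared component `b0 ~ N(0, sigma2_u0 / p)`
#' and environment-specific components `bj ~ N(0, sigma2_uj / p)`, so that
#' on the standardised-X scale the total genetic variances equal the
#' configured components (the GBLUP identity `sigma2_u = p * sigma2_b`).
#' Phenotypes are `y_j = mu_j + X (b0 + bj) + e`, `e ~ N(0, sigma2_e)`.
#'
#' Marker effects and noise are drawn from an RNG stream offset from the
#' one [simulate_allele_frequencies()] uses, so passing the same `seed` to
#' both layers cannot couple the effects or the noise to the markers.
#'
#' @param X a `"marker_matrix"`.
#' @param cfg a [sim_config()] (its `n_accessions`/`n_markers` need not
#'   match `X`; only the variance settings, environments and seed are
#'   used).
#' @return List with `data` (a `"multienv_data"`) and `truth` (list:
#'   `b0`, `bj`, `genetic_values` accession-by-environment, `mu_env`,
#'   realized `var_fractions`).
#' @export
simulate_multienv_phenotypes <- function(X, cfg = sim_config()) {
  stopifnot(inherits(X, "marker_matrix"), inherits(cfg, "sim_config"))
  if (cfg$sigma2_u0 == 0 && all(cfg$sigma2_uj == 0) && cfg$sigma2_e == 0)
    stop("all variances are zero; nothing to simulate")
  set.seed(cfg$seed + 1000003L)  # phenotype stream, distinct from genotypes
  n <- nrow(X$X); p <- X$p
  n_env <- length(cfg$env_names)
  b0 <- stats::rnorm(p, 0, sqrt(cfg$sigma2_u0 / p))
  bj <- matrix(stats::rnorm(p * n_env), p, n_env,
               dimnames = list(colnames(X$X), cfg$env_names))
  bj <- sweep(bj, 2, sqrt(cfg$sigma2_uj / p), "*")
  g <- drop(X$X %*% b0) + X$X %*% bj      # genetic value per acc x env
  Y <- sweep(g, 2, cfg$mu_env, "+") +
    matrix(stats::rnorm(n * n_env, 0, sqrt(cfg$sigma2_e)), n, n_env)
  dimnames(Y) <- list(rownames(X$X), cfg$env_names)
  vf <- vapply(seq_len(n_env), function(j) {
    gv <- stats::var(g[, j]); gv / (gv + cfg$sigma2_e)
  }, numeric(1))
  list(data = multienv_dataset(Y, X),
       truth = list(b0 = b0, bj = bj, genetic_values = g,
                    mu_env = cfg$mu_env,
                    var_fractions = stats::setNames(vf, cfg$env_names)))
}

#' Simulate phenotypes confounded with group structure
#'
#' Adds a group-level mean shift, drawn once per group from
#' `N(0, group_effect_sd^2)`, to the phenotypes of
#' [simulate_multienv_phenotypes()].  Because the marker panel itself is
#' differentiated between groups, a model trained with a group present can
#' predict the shift from the markers, while a model trained with the
#' whole group held out cannot — the mechanism by which population
#' structure inflates random-CV predictive ability.
#'
#' @param X a `"marker_matrix"`.
#' @param cfg a [sim_config()].
#' @param groups named character vector of group labels per accession
#'   (names = accession ids).
#' @param group_effect_sd standard deviation of the group mean shifts.
#' @return As [simulate_multienv_phenotypes()], with `truth$group_effects`
#'   added.
#' @export
simulate_group_structured_effects <- function(X, cfg = sim_config(), groups,
                                              group_effect_sd = 0.5) {
  base <- simulate_multienv_phenotypes(X, cfg)
  groups <- groups[rownames(X$X)]
  if (anyNA(groups)) stop("unknown group for accession(s): ",
                          paste(rownames(X$X)[is.na(groups)][1:3],
                                collapse = ", "))
  lv <- unique(groups)
  shift <- stats::setNames(stats::rnorm(length(lv), 0, group_effect_sd), lv)
  Y <- base$data$Y + shift[groups]
  base$data <- multienv_dataset(Y, X)
  base$truth$group_effects <- shift
  base
}

#' Simulate plot-level field-trial data
#'
#' Lays out a field trial over the given accession genetic values and adds
#' design effects and residual noise:
#' \describe{
#'   \item{rcbd}{`n_rep` complete blocks, block effects at `block_sd`.}
#'   \item{p_rep}{single partially replicated trial: a fraction
#'     `prep_fraction` of accessions appears twice; plots fill a grid whose
#'     rows and columns act as incomplete blocks (`row_sd`, `col_sd`); no
#'     complete-block term.}
#'   \item{alpha}{`n_rep` complete replicates, each cut into incomplete
#'     row-blocks of ~`alpha_block_size` plots (`row_sd`), with replicate
#'     effects at `block_sd`.}
#' }
#'
#' @param genetic_values named vector of true accession values.
#' @param design a [field_design()].
#' @param n_rep replicates (rcbd/alpha).
#' @param prep_fraction fraction of accessions duplicated (p_rep).
#' @param block_sd,row_sd,col_sd,residual_sd effect standard deviations.
#' @param alpha_block_size plots per incomplete block (alpha).
#' @param seed RNG seed.
#' @return Data frame of plot records: `accession`, `block`, `row`, `col`,
#'   `value`.
#' @export
simulate_plot_data <- function(genetic_values, design = field_design("rcbd"),
                               n_rep = 2, prep_fraction = 0.3,
                               block_sd = 0.2, row_sd = 0.2, col_sd = 0.2,
                               residual_sd = 0.3, alpha_block_size = 10,
                               seed = 1) {
  stopifnot(inherits(design, "field_design"))
  n <- length(genetic_values)
  if (n < 2) stop("need at least 2 accessions")
  if (n_rep < 1) stop("replicate count must be at least 1")
  acc <- names(genetic_values) %||% paste0("acc", seq_len(n))
  set.seed(seed)
  if (design$design == "rcbd") {
    df <- do.call(rbind, lapply(seq_len(n_rep), function(b) {
      data.frame(accession = sample(acc), block = paste0("B", b),
                 row = NA_character_, col = NA_character_)
    }))
    be <- stats::setNames(stats::rnorm(n_rep, 0, block_sd),
                          paste0("B", seq_len(n_rep)))
    eff <- be[df$block]
  } else if (design$design == "p_rep") {
    n_dup <- round(prep_fraction * n)
    plots <- c(acc, sample(acc, n_dup))
    plots <- sample(plots)
    n_row <- ceiling(sqrt(length(plots)))
    n_col <- ceiling(length(plots) / n_row)
    idx <- seq_along(plots) - 1
    df <- data.frame(accession = plots, block = NA_character_,
                     row = paste0("R", idx %/% n_col + 1),
                     col = paste0("C", idx %% n_col + 1))
    re <- stats::setNames(stats::rnorm(n_row, 0, row_sd),
                          paste0("R", seq_len(n_row)))
    ce <- stats::setNames(stats::rnorm(n_col, 0, col_sd),
                          paste0("C", seq_len(n_col)))
    eff <- re[df$row] + ce[df$col]
  } else {  # alpha
    df <- do.call(rbind, lapply(seq_len(n_rep), function(b) {
      ord <- sample(acc)
      ib <- paste0("B", b, ".", (seq_along(ord) - 1) %/% alpha_block_size + 1)
      data.frame(accession = ord, block = paste0("B", b), row = ib,
                 col = NA_character_)
    }))
    be <- stats::setNames(stats::rnorm(n_rep, 0, block_sd),
                          paste0("B", seq_len(n_rep)))
    ibs <- unique(df$row)
    ibe <- stats::setNames(stats::rnorm(length(ibs), 0, row_sd), ibs)
    eff <- be[df$block] + ibe[df$row]
  }
  df$value <- genetic_values[df$accession] + eff +
    stats::rnorm(nrow(df), 0, residual_sd)
  rownames(df) <- NULL
  df
}
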