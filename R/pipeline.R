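## End-to-end orchestration: simulate/ingest -> QC -> (adjust) -> fit -> CV
## -> report, driven by a YAML/list configuration, with seeded determinism
## and a manifest of everything written.

.write_tsv <- function(df, path, header) {
  con <- file(path, "w")
  writeLines(paste0("# ", header), con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", row.names = FALSE,
                                      quote = FALSE))
  close(con)
  path
}

#' Validate a pipeline run configuration
#'
#' @param config list or path to a YAML file.  Recognised blocks:
#'   `out_dir`, `seed`, `simulate` (passed to [sim_config()]; omit to read
#'   real inputs), `input` (`allele_freqs`, `phenotypes` paths), `qc`
#'   (`min_informative`, `bounds`, `max_missing_frac`), `model`
#'   (`name`, `n_iter`, `burn_in`, `thin`), `cv` (`scheme`,
#'   `test_fraction`, `n_partitions`).
#' @return The validated configuration list (class `"run_config"`).
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stop("config lacks out_dir")
  config$seed <- config$seed %||% 1L
  qc <- config$qc %||% list()
  qc$min_informative <- qc$min_informative %||% 10
  qc$bounds <- unlist(qc$bounds) %||% c(0.05, 0.95)
  qc$max_missing_frac <- qc$max_missing_frac %||% 0.05
  if (qc$bounds[1] > qc$bounds[2])
    stop("invalid QC bounds: lower bound exceeds upper bound")
  config$qc <- qc
  m <- config$model %||% list()
  m$name <- m$name %||% "mxe"
  if (!m$name %in% c("single_env", "across_env", "mxe"))
    stop("unknown model: ", m$name)
  m$n_iter <- m$n_iter %||% 25000
  m$burn_in <- m$burn_in %||% 2500
  m$thin <- m$thin %||% 5
  config$model <- m
  cv <- config$cv %||% list()
  cv$scheme <- cv$scheme %||% "cv1"
  if (!cv$scheme %in% c("cv1", "cv2", "none"))
    stop("unknown CV scheme: ", cv$scheme)
  cv$test_fraction <- cv$test_fraction %||% 0.3
  cv$n_partitions <- cv$n_partitions %||% 50
  config$cv <- cv
  if (is.null(config$simulate)) {
    inp <- config$input
    if (is.null(inp$allele_freqs) || !file.exists(inp$allele_freqs))
      stop("input allele-frequency file missing")
    if (is.null(inp$phenotypes) || !all(file.exists(unlist(inp$phenotypes))))
      stop("input phenotype file(s) missing")
  }
  class(config) <- c("run_config", "list")
  config
}

#' Run the full genomic-prediction pipeline
#'
#' Executes, in order: data simulation (or ingestion), marker QC and
#' standardisation, model fitting, cross-validation and report writing.
#' Every output file carries a header comment with the seed and the MD5 of
#' the resolved configuration, so a rerun with the same configuration and
#' seed reproduces every file bit for bit.
#'
#' @param config list or YAML path; see [run_config()].
#' @return The run manifest (list of stage outputs and file checksums),
#'   invisibly written as `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  # hash the analytic configuration only, so runs into different output
  # directories with the same settings share a hash
  hash_tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(hash_tmp), add = TRUE)
  yaml::write_yaml(unclass(cfg)[setdiff(names(cfg), "out_dir")], hash_tmp)
  cfg_md5 <- unname(tools::md5sum(hash_tmp))
  hdr <- paste0("mxegp seed=", cfg$seed, " config=", cfg_md5)
  files <- character(0)

  ## stage 1: data
  if (!is.null(cfg$simulate)) {
    sc <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed)))
    sim <- simulate_allele_frequencies(sc)
    panel <- sim$panel
    files["allele_freqs"] <- write_allele_frequencies(
      panel, file.path(cfg$out_dir, "allele_freqs.tsv"))
    meta <- data.frame(accession = names(sim$groups), group = sim$groups,
                       row.names = NULL)
    files["metadata"] <- .write_tsv(meta,
                                    file.path(cfg$out_dir, "metadata.tsv"),
                                    hdr)
  } else {
    panel <- read_allele_frequencies(cfg$input$allele_freqs)
  }

  ## stage 2: QC and standardisation
  filtered <- filter_markers(panel, cfg$qc$min_informative, cfg$qc$bounds,
                             cfg$qc$max_missing_frac)
  files["qc_report"] <- .write_tsv(attr(filtered, "qc_report"),
                                   file.path(cfg$out_dir, "qc_report.tsv"),
                                   hdr)
  X <- standardise_markers(impute_missing(filtered))

  ## stage 3: phenotypes
  if (!is.null(cfg$simulate)) {
    ph <- simulate_multienv_phenotypes(X, sc)
    Y <- apply(ph$data$Y, 2, scale_normalise)
    rownames(Y) <- rownames(ph$data$Y)
    truth <- data.frame(accession = rownames(Y),
                        ph$truth$genetic_values, check.names = FALSE)
    files["truth"] <- .write_tsv(truth, file.path(cfg$out_dir, "truth.tsv"),
                                 hdr)
  } else {
    tabs <- lapply(unlist(cfg$input$phenotypes), function(f) {
      df <- utils::read.table(f, sep = "\t", header = TRUE, comment.char = "#")
      stats::setNames(df[[2]], df[[1]])
    })
    acc <- sort(unique(unlist(lapply(tabs, names))))
    Y <- sapply(tabs, function(v) scale_normalise(v)[acc])
    rownames(Y) <- acc
    colnames(Y) <- names(cfg$input$phenotypes) %||%
      paste0("env", seq_along(tabs))
  }
  Y <- Y[intersect(rownames(Y), rownames(X$X)), , drop = FALSE]
  dat <- multienv_dataset(Y, X)

  ## stage 4: fit
  model <- cfg$model$name
  if (ncol(Y) == 1) model <- "single_env"
  st <- mcmc_settings(cfg$model$n_iter, cfg$model$burn_in, cfg$model$thin,
                      seed = cfg$seed)
  fit <- fit_gp(dat, model = model, settings = st)
  vc_tab <- .varcomp_table(fit)
  files["varcomps"] <- .write_tsv(vc_tab,
                                  file.path(cfg$out_dir, "varcomps.tsv"), hdr)
  gebv <- data.frame(accession = fit$accessions, u0 = fit$u0,
                     check.names = FALSE)
  if (!is.null(fit$u1))
    gebv <- cbind(gebv, stats::setNames(as.data.frame(fit$u1),
                                        paste0("u1_", fit$environments)))
  files["gebv"] <- .write_tsv(gebv, file.path(cfg$out_dir, "gebv.tsv"), hdr)

  ## stage 5: cross-validation
  if (cfg$cv$scheme != "none") {
    part <- if (cfg$cv$scheme == "cv2" && ncol(Y) >= 2)
      make_cv2(dat$accessions, dat$environments, cfg$cv$test_fraction,
               cfg$cv$n_partitions, seed = cfg$seed)
    else
      make_cv1(dat$accessions, dat$environments, cfg$cv$test_fraction,
               cfg$cv$n_partitions, seed = cfg$seed)
    cvr <- run_cv(dat, model, part, st)
    files["pa_long"] <- .write_tsv(cvr$results,
                                   file.path(cfg$out_dir, "pa_long.tsv"), hdr)
    files["pa_summary"] <- .write_tsv(cvr$summary,
                                      file.path(cfg$out_dir,
                                                "pa_summary.tsv"), hdr)
    files["bias"] <- .write_tsv(
      data.frame(partition = part$labels, slope = cvr$bias),
      file.path(cfg$out_dir, "bias.tsv"), hdr)
  }

  manifest <- list(config_md5 = cfg_md5, seed = cfg$seed,
                   package_version = as.character(
                     utils::packageVersion("mxegp")),
                   model = model,
                   n_accessions = nrow(Y), n_markers = X$p,
                   n_environments = ncol(Y),
                   files = as.list(files),
                   checksums = as.list(tools::md5sum(unname(files))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.varcomp_table <- function(fit) {
  vc <- fit$varcomps
  envs <- fit$environments
  sdv <- fit$varcomp_sd
  data.frame(environment = envs,
             model = fit$model,
             residual = vc$sigma2_e,
             residual_sd = sdv[["sigma2_e"]],
             marker = vc$sigma2_u0,
             marker_sd = sdv[["sigma2_u0"]],
             interaction = if (is.null(vc$sigma2_uj)) NA_real_
                           else vc$sigma2_uj,
             interaction_sd = if (is.null(vc$sigma2_uj)) NA_real_
                              else sdv[paste0("sigma2_u_", envs)],
             r2 = fit$r2$r2, r2_sd = fit$r2$r2_sd, row.names = NULL)
}

#' Collect the report tables of a finished run
#'
#' @param run output directory of [run_pipeline()] or its manifest.
#' @return List of data frames: `varcomps` (with the R2 column), `gebv`,
#'   and, when cross-validation ran, `pa_summary`, `pa_long`, `bias`.
#' @export
report_tables <- function(run) {
  dir <- if (is.list(run)) dirname(run$files$varcomps) else run
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    utils::read.table(p, sep = "\t", header = TRUE, comment.char = "#",
                      check.names = FALSE)
  }
  vc <- rd("varcomps.tsv")
  if (is.null(vc)) stop("no varcomps.tsv under ", dir, "; did the fit run?")
  out <- list(varcomps = vc, gebv = rd("gebv.tsv"),
              pa_summary = rd("pa_summary.tsv"), pa_long = rd("pa_long.tsv"),
              bias = rd("bias.tsv"))
  out[!vapply(out, is.null, logical(1))]
}
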