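## Plot-level field-trial models: per-environment BLUEs/BLUPs from
## incomplete-block designs, heritabilities, and per-environment scaling of
## the adjusted means that feed the genomic-prediction models.

#' Describe a field-trial design
#'
#' @param design `"p_rep"` (partially replicated; rows/columns act as
#'   incomplete blocks and the complete-block term is omitted), `"alpha"`
#'   (incomplete blocks within complete replicates) or `"rcbd"`
#'   (randomised complete blocks).
#' @param include_block,include_row,include_col which terms enter the
#'   model; defaults follow the design (`p_rep`: row + column, no block;
#'   `alpha`: block + row; `rcbd`: block only).
#' @return A `"field_design"` list.
#' @export
field_design <- function(design = c("p_rep", "alpha", "rcbd"),
                         include_block = NULL, include_row = NULL,
                         include_col = NULL) {
  design <- match.arg(design)
  defaults <- switch(design,
    p_rep = c(block = FALSE, row = TRUE, col = TRUE),
    alpha = c(block = TRUE, row = TRUE, col = FALSE),
    rcbd  = c(block = TRUE, row = FALSE, col = FALSE))
  if (is.null(include_block)) include_block <- defaults[["block"]]
  if (is.null(include_row)) include_row <- defaults[["row"]]
  if (is.null(include_col)) include_col <- defaults[["col"]]
  if (design == "p_rep" && include_block)
    stop("the p-rep design omits the complete-block term")
  structure(list(design = design, include_block = include_block,
                 include_row = include_row, include_col = include_col),
            class = "field_design")
}

#' Fit the plot-level mixed model of a field trial
#'
#' Fits the plot model
#' \deqn{y = \mu + g_i + b_m + ib1_n + ib2_o + \epsilon}
#' with accession (`g_i`) and complete block (`b_m`, where present) fixed
#' and the incomplete-block terms (row, column) random, by REML.  BLUEs are
#' the estimated accession means (\eqn{\mu + g_i}) from this fit; BLUPs
#' come from a second fit in which the accession is treated as a random
#' effect.  Single-replicate data with no blocking terms are passed through
#' as raw means and flagged `unadjusted`.
#'
#' @param plots data frame with columns `accession`, `value` and, as the
#'   design requires, `block`, `row`, `col`.
#' @param spec a [field_design()].
#' @return A `"field_fit"`: list with `blues`, `blups` (named vectors,
#'   both on the \eqn{\mu + g_i} scale), `blue_dev`/`blup_dev` (deviations
#'   from the overall mean), `varcomps` (named vector from the
#'   random-accession fit: `genetic`, `residual`, plus one entry per random
#'   design term), `varcomps_blue` (REML variances of the fixed-accession
#'   fit), `mu`, `n_rep` (mean replicate count), `unadjusted` flag.
#' @export
fit_field_model <- function(plots, spec = field_design("rcbd")) {
  stopifnot(is.data.frame(plots), inherits(spec, "field_design"))
  need <- c("accession", "value",
            if (spec$include_block) "block",
            if (spec$include_row) "row",
            if (spec$include_col) "col")
  miss <- setdiff(need, names(plots))
  if (length(miss) > 0)
    stop("plot table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(plots$value))) stop("non-finite plot values")
  plots$accession <- factor(plots$accession)
  if (nlevels(plots$accession) < 2) stop("need at least 2 accessions")

  # RCBD-style block is random; alpha-design complete blocks stay fixed
  rand <- c(if (spec$include_row) "row", if (spec$include_col) "col",
            if (spec$include_block && spec$design == "rcbd") "block")
  block_fixed <- spec$include_block && spec$design != "rcbd"
  for (v in c(rand, if (block_fixed) "block")) plots[[v]] <- factor(plots[[v]])

  n_rep <- mean(table(plots$accession))

  if (length(rand) == 0 && !block_fixed) {
    if (max(table(plots$accession)) == 1) {
      # single complete block: nothing to adjust for
      blues <- tapply(plots$value, plots$accession, mean)
      mu <- mean(blues)
      return(structure(list(blues = blues, blups = blues,
                            blue_dev = blues - mu, blup_dev = blues - mu,
                            varcomps = c(genetic = stats::var(blues), residual = 0),
                            mu = mu, n_rep = 1, unadjusted = TRUE),
                       class = "field_fit"))
    }
  }

  fe <- "0 + accession"
  if (block_fixed) fe <- paste(fe, "+ block")
  re <- if (length(rand) > 0)
    paste(sprintf("(1 | %s)", rand), collapse = " + ") else NULL

  # singularity guard on the fixed part
  ctr <- if (block_fixed) list(block = "contr.sum") else NULL
  mm <- stats::model.matrix(stats::as.formula(paste("~", fe)), plots,
                            contrasts.arg = ctr)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("singular fixed-effect design; confounded term(s): ",
         paste(aliased, collapse = ", "))
  }

  fit_one <- function(rhs) {
    f <- stats::as.formula(paste("value ~", rhs))
    if (is.null(re)) {
      stats::lm(f, data = plots, contrasts = ctr)
    } else {
      suppressMessages(lme4::lmer(
        stats::as.formula(paste("value ~", rhs, "+", re)),
        data = plots, REML = TRUE,
        contrasts = ctr,
        control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                    check.nobs.vs.nRE = "ignore",
                                    calc.derivs = FALSE)))
    }
  }

  # BLUE fit: accession fixed (cell-means coding; with sum-to-zero block
  # contrasts the accession coefficients are means at the average block)
  fit_blue <- fit_one(fe)
  varcomps_blue <- NULL
  if (!is.null(re)) {
    vcb <- as.data.frame(lme4::VarCorr(fit_blue))
    varcomps_blue <- stats::setNames(pmax(0, vcb$vcov),
                                     sub("Residual", "residual", vcb$grp))
  }
  cf <- if (is.null(re)) stats::coef(fit_blue) else lme4::fixef(fit_blue)
  acc_idx <- grep("^accession", names(cf))
  blues <- cf[acc_idx]
  names(blues) <- sub("^accession", "", names(blues))
  blues <- blues[levels(plots$accession)]

  # BLUP fit: accession random
  fe_b <- "1"
  if (block_fixed) fe_b <- "1 + block"
  re_b <- paste(c("(1 | accession)",
                  if (!is.null(re)) re), collapse = " + ")
  fit_blup <- suppressMessages(lme4::lmer(
    stats::as.formula(paste("value ~", fe_b, "+", re_b)),
    data = plots, REML = TRUE, contrasts = ctr,
    control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                check.nobs.vs.nRE = "ignore",
                                calc.derivs = FALSE)))
  vc <- as.data.frame(lme4::VarCorr(fit_blup))
  sigma_g2 <- vc$vcov[vc$grp == "accession"]
  sigma_e2 <- vc$vcov[vc$grp == "Residual"]
  other <- vc[!(vc$grp %in% c("accession", "Residual")), , drop = FALSE]
  varcomps <- c(genetic = max(0, sigma_g2), residual = max(0, sigma_e2),
                stats::setNames(pmax(0, other$vcov), other$grp))
  mu <- lme4::fixef(fit_blup)[["(Intercept)"]]
  g_blup <- lme4::ranef(fit_blup)$accession[, 1]
  names(g_blup) <- rownames(lme4::ranef(fit_blup)$accession)
  blups <- mu + g_blup[levels(plots$accession)]
  names(blups) <- levels(plots$accession)

  structure(list(blues = blues, blups = blups,
                 blue_dev = blues - mean(blues), blup_dev = blups - mu,
                 varcomps = varcomps, varcomps_blue = varcomps_blue,
                 mu = mu, n_rep = n_rep, unadjusted = FALSE),
            class = "field_fit")
}

#' @export
print.field_fit <- function(x, ...) {
  cat("Field-trial fit:", length(x$blues), "accessions",
      if (x$unadjusted) "(unadjusted single-block means)" else "", "\n")
  cat("  variance components:\n")
  print(round(x$varcomps, 4))
  invisible(x)
}

#' Heritability as the slope of BLUP on BLUE
#'
#' Regresses the BLUPs on the BLUEs of the same accessions; the OLS slope
#' estimates the heritability of accession means (the shrinkage factor of
#' the random-accession fit).
#'
#' @param result a `"field_fit"`.
#' @return A `"heritability"` list: `value` (clamped to \[0, 1\]),
#'   `raw_value`, `clamped` flag, `method = "blup_on_blue_slope"`.
#' @export
h2_blup_on_blue <- function(result) {
  stopifnot(inherits(result, "field_fit"))
  x <- result$blues
  y <- result$blups[names(x)]
  if (length(x) < 3) stop("need at least 3 accessions")
  sxx <- sum((x - mean(x))^2)
  if (sxx < .Machine$double.eps * 100) stop("zero variance in BLUEs")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  structure(list(value = min(1, max(0, slope)), raw_value = slope,
                 clamped = slope < 0 || slope > 1,
                 method = "blup_on_blue_slope", n_r = result$n_rep),
            class = "heritability")
}

#' Broad-sense heritability on an accession-mean basis
#'
#' \deqn{h^2_b = \sigma^2_g / (\sigma^2_g + \sigma^2_\epsilon / n_r)}
#'
#' @param sigma_g2 genetic variance.
#' @param sigma_e2 residual variance.
#' @param n_r number of replicates.
#' @return A `"heritability"` list with `method = "broad_sense"`.
#' @export
h2_broad_sense <- function(sigma_g2, sigma_e2, n_r) {
  if (sigma_g2 < 0 || sigma_e2 < 0) stop("variances must be non-negative")
  if (n_r < 1) stop("n_r must be at least 1")
  if (sigma_g2 == 0 && sigma_e2 == 0)
    stop("both variance components are zero")
  structure(list(value = sigma_g2 / (sigma_g2 + sigma_e2 / n_r),
                 raw_value = sigma_g2 / (sigma_g2 + sigma_e2 / n_r),
                 clamped = FALSE, method = "broad_sense", n_r = n_r),
            class = "heritability")
}

#' @export
print.heritability <- function(x, ...) {
  cat("Heritability (", x$method, "): ", round(x$value, 3),
      if (x$clamped) " [clamped]" else "", "\n", sep = "")
  invisible(x)
}

#' Scale and normalise per-environment BLUEs
#'
#' Standardises adjusted accession means within one environment so that
#' phenotypes entering multi-environment models are on a common scale.
#' `method = "zscore"` (default) centres and scales to mean 0, sd 1;
#' `method = "normal_scores"` maps ranks to normal quantiles.
#'
#' @param blues named numeric vector of per-accession values.
#' @param method `"zscore"` or `"normal_scores"`.
#' @return Named numeric vector with mean 0 and sd 1.
#' @export
scale_normalise <- function(blues, method = c("zscore", "normal_scores")) {
  method <- match.arg(method)
  blues <- blues[!is.na(blues)]
  if (length(blues) < 2) stop("need at least 2 accessions")
  if (method == "zscore") {
    s <- stats::sd(blues)
    if (s < .Machine$double.eps * 100) stop("zero variance in BLUEs")
    (blues - mean(blues)) / s
  } else {
    z <- stats::qnorm((rank(blues, ties.method = "average") - 0.5) /
                        length(blues))
    (z - mean(z)) / stats::sd(z)
  }
}
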