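## Allele-frequency panels: pooled-GBS genotype data where each accession is
## represented by per-marker reference-allele frequencies in [0, 1] rather
## than discrete genotype calls.

#' Construct an allele-frequency panel
#'
#' An allele-frequency panel holds an accession-by-marker matrix of
#' reference-allele frequencies in \[0, 1\] (as obtained from pooled
#' genotyping-by-sequencing), together with its quality-control state:
#' `"raw"`, `"filtered"` (after [filter_markers()]) or `"imputed"` (after
#' [impute_missing()]; no missing values remain).
#'
#' @param freqs numeric matrix, accessions in rows, markers in columns, with
#'   row and column names; values in \[0, 1\], `NA` permitted.
#' @param qc_state one of `"raw"`, `"filtered"`, `"imputed"`.
#' @return An object of class `"freq_panel"`.
#' @export
freq_panel <- function(freqs, qc_state = c("raw", "filtered", "imputed")) {
  qc_state <- match.arg(qc_state)
  freqs <- as.matrix(freqs)
  storage.mode(freqs) <- "double"
  if (is.null(rownames(freqs)))
    rownames(freqs) <- paste0("acc", seq_len(nrow(freqs)))
  if (is.null(colnames(freqs)))
    colnames(freqs) <- paste0("mk", seq_len(ncol(freqs)))
  if (anyDuplicated(rownames(freqs)))
    stop("duplicate accession ids: ",
         paste(unique(rownames(freqs)[duplicated(rownames(freqs))]), collapse = ", "))
  if (anyDuplicated(colnames(freqs)))
    stop("duplicate marker ids: ",
         paste(unique(colnames(freqs)[duplicated(colnames(freqs))]), collapse = ", "))
  bad <- which(!is.na(freqs) & (freqs < 0 | freqs > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("allele frequencies outside [0, 1] for marker ",
         colnames(freqs)[bad[1, 2]], ", accession ", rownames(freqs)[bad[1, 1]])
  if (qc_state == "imputed" && anyNA(freqs))
    stop("qc_state 'imputed' requires a panel with no missing values")
  structure(list(freqs = freqs, qc_state = qc_state), class = "freq_panel")
}

#' @export
print.freq_panel <- function(x, ...) {
  cat("Allele-frequency panel:", nrow(x$freqs), "accessions x",
      ncol(x$freqs), "markers\n")
  cat("  QC state:", x$qc_state,
      " missing:", sum(is.na(x$freqs)), "entries\n")
  invisible(x)
}

#' @export
dim.freq_panel <- function(x) dim(x$freqs)

#' Read an allele-frequency matrix from a delimited file
#'
#' Expects marker ids in the header row and accession ids in the first
#' column (accessions in rows); set `accessions_in_rows = FALSE` for the
#' transposed layout.  Empty cells and the tokens in `na_strings` become
#' missing values.
#'
#' @param path path to a TSV/CSV file.
#' @param sep field separator; guessed from the file extension by default
#'   (`.csv` gives `","`, anything else tab).
#' @param accessions_in_rows logical; if `FALSE` the file is transposed
#'   after reading.
#' @param na_strings tokens interpreted as missing.
#' @return A `"freq_panel"` with `qc_state = "raw"`.
#' @export
read_allele_frequencies <- function(path, sep = NULL,
                                    accessions_in_rows = TRUE,
                                    na_strings = c("", "NA", "NaN")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "#", quote = "\"")
  m <- as.matrix(raw)
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = dimnames(m)))
  num[m %in% na_strings] <- NA_real_
  bad <- which(!(m %in% na_strings) & is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("malformed numeric value '", m[bad[1, 1], bad[1, 2]],
         "' at accession ", rownames(m)[bad[1, 1]],
         ", marker ", colnames(m)[bad[1, 2]])
  if (!accessions_in_rows) num <- t(num)
  freq_panel(num, qc_state = "raw")
}

#' Write an allele-frequency panel to a delimited file
#'
#' Inverse of [read_allele_frequencies()]: marker ids in the header,
#' accession ids in the first column, missing values as empty cells.
#'
#' @param panel a `"freq_panel"`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_allele_frequencies <- function(panel, path, sep = "\t") {
  stopifnot(inherits(panel, "freq_panel"))
  df <- data.frame(accession = rownames(panel$freqs), panel$freqs,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Quality-filter markers of an allele-frequency panel
#'
#' A marker is retained when all three rules hold:
#' \enumerate{
#'   \item at least `min_informative` accessions have a non-missing
#'     frequency inside `bounds` (inclusive);
#'   \item its mean frequency over non-missing accessions lies inside
#'     `bounds` (inclusive);
#'   \item its fraction of missing values is at most `max_missing_frac`.
#' }
#' The surviving set is the intersection of the three rules, so the order
#' in which they are applied does not matter.  A per-marker QC report is
#' attached as attribute `"qc_report"`.
#'
#' @param panel a raw `"freq_panel"`.
#' @param min_informative minimum count of accessions with frequency inside
#'   `bounds`.
#' @param bounds inclusive lower/upper frequency bounds.
#' @param max_missing_frac maximum tolerated fraction of missing entries.
#' @return A `"freq_panel"` with `qc_state = "filtered"`, marker order
#'   preserved.
#' @export
filter_markers <- function(panel, min_informative = 10,
                           bounds = c(0.05, 0.95), max_missing_frac = 0.05) {
  stopifnot(inherits(panel, "freq_panel"))
  if (panel$qc_state != "raw")
    stop("filter_markers() expects a panel with qc_state 'raw', got '",
         panel$qc_state, "'")
  if (bounds[1] > bounds[2]) stop("invalid bounds: lower > upper")
  f <- panel$freqs
  n_inf <- colSums(!is.na(f) & f >= bounds[1] & f <= bounds[2])
  mu <- colMeans(f, na.rm = TRUE)
  miss <- colMeans(is.na(f))
  pass_inf <- n_inf >= min_informative
  pass_mean <- !is.nan(mu) & mu >= bounds[1] & mu <= bounds[2]
  pass_miss <- miss <= max_missing_frac
  keep <- pass_inf & pass_mean & pass_miss
  report <- data.frame(marker = colnames(f), n_informative = n_inf,
                       mean_freq = mu, missing_frac = miss,
                       pass_informative = pass_inf, pass_mean = pass_mean,
                       pass_missing = pass_miss, retained = keep,
                       row.names = NULL)
  if (!any(keep))
    stop("no markers survive filtering (", ncol(f), " markers examined)")
  out <- freq_panel(f[, keep, drop = FALSE], qc_state = "raw")
  out$qc_state <- "filtered"
  attr(out, "qc_report") <- report
  out
}

#' Impute missing allele frequencies by the marker mean
#'
#' Each missing entry is replaced by the mean frequency of its marker over
#' the non-missing accessions.
#'
#' @param panel a filtered `"freq_panel"`.
#' @return A `"freq_panel"` with `qc_state = "imputed"` and no missing
#'   values.
#' @export
impute_missing <- function(panel) {
  stopifnot(inherits(panel, "freq_panel"))
  if (panel$qc_state != "filtered")
    stop("impute_missing() expects a filtered panel, got '",
         panel$qc_state, "'")
  f <- panel$freqs
  all_miss <- colSums(!is.na(f)) == 0
  if (any(all_miss))
    stop("marker(s) with all entries missing: ",
         paste(colnames(f)[all_miss], collapse = ", "))
  if (anyNA(f)) {
    mu <- colMeans(f, na.rm = TRUE)
    idx <- which(is.na(f), arr.ind = TRUE)
    f[idx] <- mu[idx[, 2]]
  }
  out <- freq_panel(f, qc_state = "imputed")
  attr(out, "qc_report") <- attr(panel, "qc_report")
  out
}

#' Centre and standardise a panel into a marker matrix
#'
#' Each marker column is centred by subtracting its mean frequency and
#' scaled by its standard deviation (sample convention, n-1 denominator),
#' giving the matrix X used by all GBLUP models.  Pass the `center` and
#' `scale` of a training panel to project held-out accessions onto the
#' training scale.
#'
#' @param panel an imputed `"freq_panel"`.
#' @param center,scale optional per-marker means/sds from a reference
#'   (training) standardisation; taken from `panel` itself by default.
#' @return An object of class `"marker_matrix"`: list with `X` (accession
#'   by marker), `center`, `scale`, `p` (marker count).
#' @export
standardise_markers <- function(panel, center = NULL, scale = NULL) {
  stopifnot(inherits(panel, "freq_panel"))
  if (panel$qc_state != "imputed")
    stop("standardise_markers() expects an imputed panel, got '",
         panel$qc_state, "'")
  f <- panel$freqs
  if (is.null(center)) center <- colMeans(f)
  if (is.null(scale)) scale <- apply(f, 2, stats::sd)
  if (any(scale < .Machine$double.eps * 100)) {
    zv <- colnames(f)[scale < .Machine$double.eps * 100]
    stop("zero-variance marker(s): ", paste(utils::head(zv, 5), collapse = ", "))
  }
  X <- sweep(sweep(f, 2, center, "-"), 2, scale, "/")
  structure(list(X = X, center = center, scale = scale, p = ncol(X)),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("Standardised marker matrix:", nrow(x$X), "accessions x", x$p,
      "markers\n")
  invisible(x)
}

#' Genomic relationship matrix G = XX'/p
#'
#' VanRaden-style genomic relationship matrix from a standardised marker
#' matrix: `G = X X' / p` where `p` is the marker count.  Symmetric and
#' positive semi-definite by construction.
#'
#' @param X a `"marker_matrix"` (or plain standardised matrix).
#' @return An object of class `"grm"`: the accession-by-accession matrix
#'   with attribute `p`.
#' @export
compute_grm <- function(X) {
  M <- if (inherits(X, "marker_matrix")) X$X else as.matrix(X)
  p <- ncol(M)
  if (p == 0) stop("cannot build a relationship matrix from zero markers")
  G <- tcrossprod(M) / p
  G <- (G + t(G)) / 2
  structure(G, p = p, class = c("grm", "matrix", "array"))
}

#' @export
print.grm <- function(x, ...) {
  cat("Genomic relationship matrix:", nrow(x), "accessions, built from",
      attr(x, "p"), "markers\n")
  cat("  mean diagonal:", round(mean(diag(x)), 3), "\n")
  invisible(x)
}
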