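# Expression-matrix preparation: quantile normalization, per-line log fold
# changes, paired t tests, enrichment scores.

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common reference distribution of mean
#' order statistics; ties within a column receive the mean of the
#' corresponding reference quantiles. Delegates to
#' [limma::normalizeQuantiles()] with tie averaging.
#'
#' @param m numeric matrix, probes x samples, at least 2 samples.
#' @return matrix of the same dimension and dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("argument error: need >= 2 samples")
  const <- apply(m, 2, function(x) diff(range(x)) == 0)
  if (any(const))
    warning("constant column(s) in expression matrix: ",
            paste(utils::head(colnames(m)[const], 5), collapse = ", "))
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Per-line log fold change with an intensity floor
#'
#' `fc = log2(max(treated, floor) / max(untreated, floor))`. The floor guards
#' background-subtracted intensities at or below zero; with both values
#' floored the result is antisymmetric in treated/untreated.
#'
#' @param treated,untreated paired intensity vectors.
#' @param floor intensity floor (default 1).
#' @return log2 fold changes.
#' @export
log_fold_change <- function(treated, untreated, floor = 1) {
  if (length(treated) != length(untreated))
    stop("pairing error: treated/untreated length mismatch")
  log2(pmax(treated, floor) / pmax(untreated, floor))
}

#' Per-probe, per-line fold-change table for both drugs
#'
#' Expects sample columns named `line:condition` with conditions `untreated`,
#' `imatinib`, `omacetaxine`; every line must carry all three conditions.
#'
#' @param m expression matrix (probes x samples), typically
#'   quantile-normalized.
#' @param floor intensity floor passed to [log_fold_change()].
#' @return Object of class `fold_change_table`: list with `probe_ids`,
#'   `line_ids`, and probes x lines matrices `ifc` (imatinib) and `ofc`
#'   (omacetaxine).
#' @export
fold_change_table <- function(m, floor = 1) {
  parts <- strsplit(colnames(m), ":", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("pairing error: sample columns must be named line:condition")
  line <- vapply(parts, `[`, "", 1)
  cond <- vapply(parts, `[`, "", 2)
  lines <- unique(line)
  col_of <- function(l, cn) {
    j <- which(line == l & cond == cn)
    if (length(j) != 1)
      stop("pairing error: line ", l, " lacks a unique '", cn, "' sample")
    j
  }
  fc <- function(cn) {
    out <- vapply(lines, function(l)
      log_fold_change(m[, col_of(l, cn)], m[, col_of(l, "untreated")], floor),
      numeric(nrow(m)))
    dimnames(out) <- list(rownames(m), lines)
    out
  }
  structure(list(probe_ids = rownames(m), line_ids = lines,
                 ifc = fc("imatinib"), ofc = fc("omacetaxine")),
            class = "fold_change_table")
}

#' Paired Student's t test
#'
#' Two-sided classical paired t on matched vectors (df = n - 1).
#'
#' @param treated,untreated matched vectors, n >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
paired_t_test <- function(treated, untreated) {
  if (length(treated) != length(untreated))
    stop("pairing error: length mismatch")
  d <- treated - untreated
  if (stats::sd(d) == 0) stop("degenerate error: zero variance of differences")
  ht <- stats::t.test(treated, untreated, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Mean enrichment score of a p-value set
#'
#' The average of `-log10(p)`; exact zeros are clamped to the smallest
#' positive double with a warning.
#'
#' @param pvalues p-values in `[0, 1]` (zeros clamped).
#' @return nonnegative scalar.
#' @export
enrichment_score <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1)) stop("argument error: p outside [0, 1]")
  if (any(pvalues == 0)) {
    warning("p = 0 clamped to smallest positive double")
    pvalues[pvalues == 0] <- .Machine$double.xmin
  }
  mean(-log10(pvalues))
}

#' Read / write an expression matrix
#'
#' First column = probe id, remaining columns = samples named
#' `line:condition`. The delimiter (tab or comma) is autodetected on read; the
#' writer preserves column order.
#'
#' @param path file path.
#' @return numeric matrix with probe rownames.
#' @export
read_expression <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          row.names = 1)
  as.matrix(df)
}

#' @rdname read_expression
#' @param m expression matrix.
#' @param sep delimiter, tab by default.
#' @export
write_expression <- function(m, path, sep = "\t") {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
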