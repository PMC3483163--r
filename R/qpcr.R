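# qPCR validation: replicate QC, 2^-ddCt relative quantitation, platform
# concordance with the microarray fold changes.

#' Replicate quality control for cycle-threshold (CT) values
#'
#' Triplicates with sample SD <= 0.3 cycles are averaged. If the triplicate SD
#' exceeds 0.3, the duplicate pair with the smallest SD is assessed; if that
#' pair's SD also exceeds 0.3 the sample is excluded. A single replicate is
#' accepted as-is (its SD is undefined).
#'
#' @param replicates 1-3 CT values (cycles, in (0, 45)).
#' @param max_sd QC threshold on the replicate SD (default 0.3 cycles).
#' @return list with `ct` (accepted mean, `NA` if excluded), `excluded`,
#'   `n_used`.
#' @export
qc_ct <- function(replicates, max_sd = 0.3) {
  cts <- replicates[!is.na(replicates)]
  if (length(cts) == 0 || length(cts) > 3)
    stop("argument error: need 1-3 CT replicates")
  if (any(cts <= 0 | cts >= 45)) stop("argument error: CT outside (0, 45)")
  if (length(cts) == 1)
    return(list(ct = cts, excluded = FALSE, n_used = 1L))
  if (length(cts) == 3) {
    if (stats::sd(cts) <= max_sd)
      return(list(ct = mean(cts), excluded = FALSE, n_used = 3L))
    pairs <- utils::combn(3, 2)
    sds <- apply(pairs, 2, function(j) stats::sd(cts[j]))
    cts <- cts[pairs[, which.min(sds)]]
  }
  if (stats::sd(cts) <= max_sd)
    list(ct = mean(cts), excluded = FALSE, n_used = 2L)
  else
    list(ct = NA_real_, excluded = TRUE, n_used = 0L)
}

#' Relative quantitation by the 2^-ddCt method
#'
#' `ddCt = (CT_target - CT_reference)_treated - (CT_target -
#' CT_reference)_control`; relative quantity `rq = 2^-ddCt` assumes perfect
#' doubling per cycle. Any QC-excluded input (NA) propagates to an excluded
#' result.
#'
#' @param target_treated,ref_treated,target_control,ref_control mean CTs
#'   accepted by [qc_ct()].
#' @return list with `ddct`, `rq`, `excluded`.
#' @export
ddct <- function(target_treated, ref_treated, target_control, ref_control) {
  cts <- c(target_treated, ref_treated, target_control, ref_control)
  if (anyNA(cts))
    return(list(ddct = NA_real_, rq = NA_real_, excluded = TRUE))
  dd <- (target_treated - ref_treated) - (target_control - ref_control)
  list(ddct = dd, rq = 2^(-dd), excluded = FALSE)
}

#' Correct microarray log fold changes for the reference gene
#'
#' Subtracts the reference probe's log fold change from every gene's log fold
#' change per sample, making the microarray values directly comparable with
#' reference-normalized qPCR quantities.
#'
#' @param fc genes x samples matrix of log fold changes (reference row
#'   included or supplied separately).
#' @param reference_fc vector of the reference gene's log fold change per
#'   sample.
#' @return corrected matrix.
#' @export
reference_correct_fc <- function(fc, reference_fc) {
  fc <- as.matrix(fc)
  if (ncol(fc) != length(reference_fc))
    stop("argument error: reference_fc length must match sample count")
  sweep(fc, 2, reference_fc, "-")
}

#' Microarray / qPCR concordance correlation
#'
#' Pearson correlation if both margins pass a Shapiro-Wilk normality test at
#' `normality_alpha`, Spearman otherwise; two-sided.
#'
#' @param micro_fc reference-corrected microarray log fold changes.
#' @param qpcr_log_rq matched `log2(rq)` values from qPCR.
#' @param normality_alpha Shapiro-Wilk level gating the method (default 0.05).
#' @return list with `estimate`, `p`, `method`, `n`.
#' @export
platform_concordance <- function(micro_fc, qpcr_log_rq, normality_alpha = 0.05) {
  ok <- is.finite(micro_fc) & is.finite(qpcr_log_rq)
  x <- micro_fc[ok]; y <- qpcr_log_rq[ok]
  if (length(x) < 3) stop("argument error: need >= 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined-correlation error: constant margin")
  normal <- function(v) length(v) <= 5000 &&
    stats::shapiro.test(v)$p.value > normality_alpha
  method <- if (normal(x) && normal(y)) "pearson" else "spearman"
  ht <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(estimate = unname(ht$estimate), p = ht$p.value, method = method,
       n = length(x))
}

#' Read a CT table
#'
#' TSV with columns `sample_id`, `gene`, `condition`, `ct1`, `ct2`, `ct3`
#' (blanks allowed).
#'
#' @param path file path.
#' @return data.frame of CT records.
#' @export
read_ct <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  req <- c("sample_id", "gene", "condition", "ct1")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("ct format error: missing column(s) ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_ct
#' @param ct data.frame of CT records.
#' @export
write_ct <- function(ct, path) {
  utils::write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run QC and relative quantitation over a CT table
#'
#' For every sample x target-gene x treated-condition combination, applies
#' [qc_ct()] to target and reference CTs in both the treated and untreated
#' condition and computes [ddct()].
#'
#' @param ct CT table as from [read_ct()].
#' @param reference_gene endogenous control gene name (e.g. `"HPRT1"`).
#' @return data.frame with `sample_id`, `gene`, `condition`, `ddct`, `rq`,
#'   `excluded`.
#' @export
relative_quantitation <- function(ct, reference_gene = "HPRT1") {
  ct_cols <- intersect(c("ct1", "ct2", "ct3"), names(ct))
  mean_ct <- function(sample, gene, condition) {
    row <- ct[ct$sample_id == sample & ct$gene == gene &
              ct$condition == condition, ct_cols, drop = FALSE]
    if (nrow(row) != 1) return(NA_real_)
    qc_ct(as.numeric(row[1, ]))$ct
  }
  targets <- setdiff(unique(ct$gene), reference_gene)
  treated_conds <- setdiff(unique(ct$condition), "untreated")
  grid <- expand.grid(sample_id = unique(ct$sample_id), gene = targets,
                      condition = treated_conds, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    r <- ddct(mean_ct(g$sample_id, g$gene, g$condition),
              mean_ct(g$sample_id, reference_gene, g$condition),
              mean_ct(g$sample_id, g$gene, "untreated"),
              mean_ct(g$sample_id, reference_gene, "untreated"))
    data.frame(g, ddct = r$ddct, rq = r$rq, excluded = r$excluded)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
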