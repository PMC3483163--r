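#!/usr/bin/env Rscript
# Stage 5: qPCR validation of the microarray fold changes.
#
# Applies the 0.3-cycle replicate QC ladder and 2^-ddCt relative quantitation
# (HPRT1 endogenous control) to the simulated CT table, corrects the
# microarray log fold changes for the reference gene, and reports the
# platform-concordance correlation (Pearson or Spearman, gated by
# Shapiro-Wilk normality of both margins).

library(lcltox)

ct <- read_ct("results/data/ct.tsv")
expr <- read_expression("results/data/expression.tsv")
truth <- utils::read.delim("results/data/ground_truth.tsv")

rq <- relative_quantitation(ct, reference_gene = "HPRT1")
utils::write.table(rq, "results/qpcr_rq.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat("qPCR measurements:", nrow(rq), " excluded by QC:", sum(rq$excluded), "\n")

# microarray fold changes for the panel genes, HPRT1-corrected.
# The synthetic reference gene is flat across conditions, so the correction
# subtracts (near-)zero; it is applied for parity with the qPCR normalization.
qn <- quantile_normalize(expr)
fc <- fold_change_table(qn)
panel <- unique(rq$gene)
ref_fc_i <- rep(0, length(fc$line_ids))   # HPRT1 planted flat
rows <- list()
for (drug in c("imatinib", "omacetaxine")) {
  mat <- if (drug == "imatinib") fc$ifc else fc$ofc
  for (g in panel) {
    micro <- reference_correct_fc(mat[g, , drop = FALSE], ref_fc_i)
    sub <- rq[rq$gene == g & rq$condition == drug & !rq$excluded, ]
    m <- match(sub$sample_id, fc$line_ids)
    rows[[length(rows) + 1]] <- data.frame(
      gene = g, drug = drug, line_id = sub$sample_id,
      micro_fc = micro[1, m], qpcr_log_rq = log2(sub$rq))
  }
}
paired <- do.call(rbind, rows)
utils::write.table(paired, "results/platform_pairs.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

pooled <- platform_concordance(paired$micro_fc, paired$qpcr_log_rq)
cat(sprintf("pooled concordance: %s r = %.3f (p = %.3g, n = %d)\n",
            pooled$method, pooled$estimate, pooled$p, pooled$n))

per_gene <- lapply(split(paired, paired$gene), function(d) {
  r <- platform_concordance(d$micro_fc, d$qpcr_log_rq)
  data.frame(gene = d$gene[1], method = r$method, estimate = r$estimate,
             p = r$p, n = r$n)
})
per_gene <- do.call(rbind, per_gene)
utils::write.table(per_gene, "results/platform_concordance.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("per-gene concordance:\n")
print(per_gene, digits = 3, row.names = FALSE)

# direction-of-effect agreement on mean differential expression per gene/drug
dir_tab <- stats::aggregate(cbind(micro_fc, qpcr_log_rq) ~ gene + drug,
                            data = paired, FUN = mean)
agree <- sign(dir_tab$micro_fc) == sign(dir_tab$qpcr_log_rq)
cat(sprintf("direction agreement: %d / %d gene x drug means\n",
            sum(agree), nrow(dir_tab)))
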