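#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# Emulates the study design: 17 pedigrees of 6-10 members (one MZ pair,
# sibling and first-cousin pairs among the assayed lines), heritable imatinib
# log-IC50 (h2 = 0.60) vs non-heritable omacetaxine (h2 = 0), triplicate
# alamarBlue plates on the study dose grids, a 2,000-probe expression matrix
# with the published four-cluster (iFC, oFC) geometry planted over ~9% of
# probes, and a 5-gene qPCR CT panel. Everything downstream reads the files
# written here.

library(lcltox)

out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

config <- sim_config(seed = 20260925)
st <- simulate_study(config)

write_pedigree(st$pedigree, file.path(out_dir, "pedigree.tsv"))
write_plates(st$plates, file.path(out_dir, "plates.tsv"))
write_expression(st$expression, file.path(out_dir, "expression.tsv"))
write_ct(st$ct, file.path(out_dir, "ct.tsv"))
utils::write.table(st$expression_truth, file.path(out_dir, "ground_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(st$assayed_ids, file.path(out_dir, "assayed_ids.txt"))
utils::write.table(
  data.frame(line_id = names(st$true_log_ic50$imatinib),
             log_ic50_imatinib = st$true_log_ic50$imatinib,
             log_ic50_omacetaxine = st$true_log_ic50$omacetaxine),
  file.path(out_dir, "true_log_ic50.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

cat("cohort:", nrow(st$pedigree), "individuals in",
    length(unique(st$pedigree$family_id)), "pedigrees;",
    length(st$assayed_ids), "assayed lines\n")
cat("plates:", nrow(st$plates), "wells;  expression:",
    nrow(st$expression), "probes x", ncol(st$expression), "samples\n")
cat("planted non-null probes:", sum(st$expression_truth$cluster > 0),
    sprintf("(%.1f%%)\n", 100 * mean(st$expression_truth$cluster > 0)))
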