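#!/usr/bin/env Rscript
# Stage 2: plate absorbances -> percent viability -> 4PL fits -> IC ladder
# and SDR slopes.
#
# Replicate absorbances are averaged before the viability equation; each
# line x drug gets a four-parameter logistic fit on log10 dose, inhibitory
# concentrations at thresholds 10-90%, and the sensitivity-of-drug-response
# (SDR) slope of viability on log10 dose.

library(lcltox)

plates <- read_plates("results/data/plates.tsv")
vp <- average_replicates(plates)
thresholds <- seq(10, 90, 10)

rows <- list()
for (drug in setdiff(unique(vp$drug), "none")) {
  vd <- vp[vp$drug == drug, ]
  for (l in unique(vd$line_id)) {
    vl <- vd[vd$line_id == l, ]
    fit <- tryCatch(fit_4pl(vl$dose_molar, vl$viability),
                    error = function(e) NULL)
    if (is.null(fit)) next
    ic <- vapply(thresholds, function(th)
      tryCatch(inhibitory_concentration(fit, th),
               error = function(e) NA_real_), numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      line_id = l, drug = drug, threshold = thresholds, ic_molar = ic,
      log_ic50 = fit$log_ic50, hill = fit$hill)
  }
}
ic_table <- do.call(rbind, rows)
utils::write.table(ic_table, "results/ic_table.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

sdr_tab <- sdr_table(plates)
utils::write.table(sdr_tab, "results/sdr.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

ic20 <- ic_table[ic_table$threshold == 20, ]
for (drug in unique(ic20$drug))
  cat(sprintf("%s IC20: %.3g - %.3g M (mean %.3g M, %d lines)\n", drug,
              min(ic20$ic_molar[ic20$drug == drug], na.rm = TRUE),
              max(ic20$ic_molar[ic20$drug == drug], na.rm = TRUE),
              mean(ic20$ic_molar[ic20$drug == drug], na.rm = TRUE),
              sum(ic20$drug == drug)))
cat("SDR slopes all negative:", all(sdr_tab$slope < 0), "\n")
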