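# Study-level orchestration: the heritability-of-IC report (Table-1 shape)
# and the differential-expression / clustering / association study.

#' Heritability of inhibitory concentrations across a threshold ladder
#'
#' For each drug and cell line: average replicate absorbances, convert to
#' percent viability, fit the 4PL dose-response curve, and extract IC doses at
#' the requested inhibition thresholds. Each threshold's log10 IC trait is
#' then tested for heritability on the pedigree (inverse normal transform,
#' polygenic vs sporadic ML fits, boundary-mixture LRT).
#'
#' @param ped a [pedigree] object covering the assayed lines.
#' @param plates plate records (see [read_plates()]).
#' @param thresholds percent-inhibition ladder (default 10..90 by 10).
#' @param X optional covariate matrix aligned with the assayed lines.
#' @return data.frame with one row per drug x threshold: `drug`, `threshold`,
#'   `mean_dose` (molar), `n`, `h2`, `statistic`, `p`.
#' @export
run_heritability_study <- function(ped, plates, thresholds = seq(10, 90, 10),
                                   X = NULL) {
  vp <- average_replicates(plates)
  drugs <- setdiff(unique(vp$drug), "none")
  out <- list()
  for (drug in drugs) {
    vd <- vp[vp$drug == drug, , drop = FALSE]
    lines <- unique(vd$line_id)
    ic <- matrix(NA_real_, length(lines), length(thresholds),
                 dimnames = list(lines, thresholds))
    for (l in lines) {
      vl <- vd[vd$line_id == l, , drop = FALSE]
      fit <- tryCatch(fit_4pl(vl$dose_molar, vl$viability),
                      error = function(e) NULL)
      if (is.null(fit)) next
      for (j in seq_along(thresholds)) {
        ic[l, j] <- tryCatch(inhibitory_concentration(fit, thresholds[j]),
                             error = function(e) NA_real_)
      }
    }
    for (j in seq_along(thresholds)) {
      ok <- !is.na(ic[, j])
      ids <- lines[ok]
      K <- kinship_matrix(ped, ids)
      Xj <- if (is.null(X)) NULL else X[ids, , drop = FALSE]
      ht <- heritability_test(log10(ic[ok, j]), Xj, K)
      out[[length(out) + 1]] <- data.frame(
        drug = drug, threshold = thresholds[j],
        mean_dose = mean(ic[ok, j]), n = sum(ok),
        h2 = ht$h2, statistic = ht$statistic, p = ht$p)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' SDR (sensitivity of drug response) per line and drug
#'
#' @param plates plate records.
#' @return data.frame `line_id`, `drug`, `slope`, `intercept`, `n_points`.
#' @export
sdr_table <- function(plates) {
  vp <- average_replicates(plates)
  grp <- split(vp, list(vp$line_id, vp$drug), drop = TRUE)
  out <- lapply(grp, function(g) {
    s <- sdr(g$dose_molar, g$viability)
    data.frame(line_id = g$line_id[1], drug = g$drug[1],
               slope = s$slope, intercept = s$intercept,
               n_points = s$n_points)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$drug, res$line_id), , drop = FALSE]
}

#' Differential-expression, clustering and SDR-association study
#'
#' Quantile-normalizes the expression matrix, computes per-line iFC/oFC,
#' tests each probe's mean fold change (kinship-corrected LRT by default),
#' applies Benjamini-Hochberg per drug, k-means clusters the significant
#' probes in (mean iFC, mean oFC) space, and regresses each drug's SDR on the
#' significant probes' fold changes in the polygenic model.
#'
#' @param expr probes x samples intensity matrix, columns `line:condition`.
#' @param ped a [pedigree] covering the assayed lines.
#' @param sdr_tab optional output of [sdr_table()] for the association stage.
#' @param X optional covariates aligned with the assayed lines.
#' @param alpha FDR level (default 0.05).
#' @param k clusters (default 4).
#' @param seed,restarts k-means initialization control.
#' @param use_kinship kinship-corrected mean tests (default TRUE).
#' @param floor intensity floor for fold changes.
#' @return list with `volcano` (per-probe means, p, q per drug), `clusters`
#'   (`cluster_report` over significant probes), `cluster_summary`, `overlap`,
#'   `association` (per significant probe x drug coefficients and p), and the
#'   `fold_changes` table.
#' @export
run_dex_study <- function(expr, ped, sdr_tab = NULL, X = NULL, alpha = 0.05,
                          k = 4, seed = 17, restarts = 100,
                          use_kinship = TRUE, floor = 1) {
  qn <- quantile_normalize(expr)
  fc <- fold_change_table(qn, floor = floor)
  lines <- fc$line_ids
  K <- kinship_matrix(ped, lines)
  ke <- kinship_eigen(K)
  Xl <- if (is.null(X)) NULL else X[lines, , drop = FALSE]

  test_drug <- function(mat) {
    p <- vapply(seq_len(nrow(mat)), function(i) {
      tryCatch(mean_fc_test(mat[i, ], Xl, ke, use_kinship = use_kinship)$p,
               error = function(e) NA_real_)
    }, numeric(1))
    data.frame(mean_fc = rowMeans(mat), p = p)
  }
  vi <- test_drug(fc$ifc)
  vo <- test_drug(fc$ofc)
  bh_safe <- function(p) {
    out <- data.frame(q = rep(NA_real_, length(p)),
                      significant = rep(FALSE, length(p)))
    ok <- !is.na(p)
    if (any(ok)) out[ok, ] <- bh_qvalues(p[ok], alpha)[, c("q", "significant")]
    out
  }
  qi <- bh_safe(vi$p)
  qo <- bh_safe(vo$p)
  volcano <- data.frame(probe_id = fc$probe_ids,
                        ifc = vi$mean_fc, p_i = vi$p, q_i = qi$q,
                        sig_i = qi$significant,
                        ofc = vo$mean_fc, p_o = vo$p, q_o = qo$q,
                        sig_o = qo$significant)

  sig <- volcano$sig_i | volcano$sig_o
  ov <- significant_overlap(volcano$probe_id[volcano$sig_i],
                            volcano$probe_id[volcano$sig_o],
                            volcano$probe_id)
  clusters <- NULL; csum <- NULL
  if (sum(sig) >= k) {
    pts <- cbind(ifc = volcano$ifc[sig], ofc = volcano$ofc[sig])
    clusters <- kmeans_fc(pts, k = k, seed = seed, restarts = restarts)
    csum <- cluster_summary(clusters, pts,
                            q_i = volcano$q_i[sig], q_o = volcano$q_o[sig])
  }

  association <- NULL
  if (!is.null(sdr_tab)) {
    assoc_one <- function(drug, mat, sig_flag) {
      st <- sdr_tab[sdr_tab$drug == drug, , drop = FALSE]
      sv <- stats::setNames(st$slope, st$line_id)[lines]
      idx <- which(sig_flag)
      res <- lapply(idx, function(i) {
        a <- tryCatch(fc_sdr_association(sv, mat[i, ], Xl, ke),
                      error = function(e) list(coefficient = NA_real_,
                                               statistic = NA_real_,
                                               p = NA_real_))
        data.frame(probe_id = fc$probe_ids[i], drug = drug,
                   coefficient = a$coefficient, statistic = a$statistic,
                   p = a$p)
      })
      do.call(rbind, res)
    }
    association <- rbind(assoc_one("imatinib", fc$ifc, volcano$sig_i),
                         assoc_one("omacetaxine", fc$ofc, volcano$sig_o))
    if (!is.null(association) && nrow(association) > 0) {
      ok <- !is.na(association$p)
      association$q <- NA_real_
      association$q[ok] <- stats::p.adjust(association$p[ok], method = "BH")
      rownames(association) <- NULL
    }
  }

  list(volcano = volcano, clusters = clusters, cluster_summary = csum,
       overlap = ov, association = association, fold_changes = fc)
}
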