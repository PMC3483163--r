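# Synthetic-data generators reproducing the study's statistical structure:
# 17 pedigrees of 6-10 members with sibling, third-degree and one MZ pair;
# heritable log-IC traits; alamarBlue plate absorbances over the study dose
# grids; expression matrices with a planted four-cluster (iFC, oFC) structure
# and kinship-correlated residuals; qPCR CT triplicates. Every generator is a
# pure function of (config, RNG state).

#' Simulation configuration
#'
#' Defaults mirror the study design: 17 pedigrees of 6-10 members (~110
#' individuals), 55 assayed lines, imatinib IC heritability 0.60 and
#' omacetaxine 0, the published four cluster centers in (iFC, oFC) space with
#' cluster fractions proportional to the published cluster sizes, and the
#' study dose grids.
#'
#' @param seed integer RNG seed.
#' @param n_families number of pedigrees.
#' @param family_size_range inclusive (min, max) family size.
#' @param n_assayed expression-assayed subset size.
#' @param h2_ic_imatinib,h2_ic_omacetaxine true heritability of log IC50.
#' @param n_probes probe count of the synthetic array.
#' @param cluster_centers 4 x 2 matrix of true (iFC, oFC) cluster means.
#' @param cluster_fractions fractions of probes in clusters 1-4.
#' @param null_fraction fraction of null probes (fractions sum to 1).
#' @param fc_noise_sd per-probe scatter of true cluster means.
#' @param fc_line_sd per-line residual SD of fold changes around the probe
#'   mean.
#' @param h2r_range interval from which per-probe FC heritability is drawn.
#' @param dose_grid_imatinib,dose_grid_omacetaxine dose grids (molar).
#' @param mean_log_ic50 named per-drug mean of true log10 IC50.
#' @param sd_log_ic50 SD of true log10 IC50 across lines.
#' @param hill true Hill slope of the generating curves.
#' @param plate_noise_sd replicate viability noise (percent points).
#' @param ct_noise_sd CT replicate noise (cycles).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_families = 17,
                       family_size_range = c(6, 10),
                       n_assayed = 55,
                       h2_ic_imatinib = 0.60,
                       h2_ic_omacetaxine = 0.0,
                       n_probes = 2000,
                       cluster_centers = matrix(c(-0.02, 0.26,
                                                  -0.08, -0.35,
                                                   0.36, 0.10,
                                                   0.13, 0.50),
                                                4, 2, byrow = TRUE),
                       cluster_fractions = c(0.0282, 0.0411, 0.0088, 0.0132),
                       null_fraction = 1 - sum(cluster_fractions),
                       fc_noise_sd = 0.08,
                       fc_line_sd = 0.40,
                       h2r_range = c(0.2, 0.6),
                       dose_grid_imatinib = c(2, 10, 50, 75, 100, 150, 200) * 1e-6,
                       dose_grid_omacetaxine = c(5, 10, 25, 50, 75, 100, 500) * 1e-9,
                       mean_log_ic50 = c(imatinib = -3.9, omacetaxine = -7.0),
                       sd_log_ic50 = 0.25,
                       hill = 1,
                       plate_noise_sd = 2,
                       ct_noise_sd = 0.1) {
  cfg <- list(seed = seed, n_families = n_families,
              family_size_range = family_size_range, n_assayed = n_assayed,
              h2_ic_imatinib = h2_ic_imatinib,
              h2_ic_omacetaxine = h2_ic_omacetaxine,
              n_probes = n_probes, cluster_centers = cluster_centers,
              cluster_fractions = cluster_fractions,
              null_fraction = null_fraction, fc_noise_sd = fc_noise_sd,
              fc_line_sd = fc_line_sd, h2r_range = h2r_range,
              dose_grids = list(imatinib = dose_grid_imatinib,
                                omacetaxine = dose_grid_omacetaxine),
              mean_log_ic50 = mean_log_ic50, sd_log_ic50 = sd_log_ic50,
              hill = hill, plate_noise_sd = plate_noise_sd,
              ct_noise_sd = ct_noise_sd)
  if (abs(sum(cfg$cluster_fractions) + cfg$null_fraction - 1) > 1e-8)
    stop("configuration error: cluster_fractions + null_fraction must sum to 1")
  if (any(c(cfg$cluster_fractions, cfg$null_fraction) < 0))
    stop("configuration error: fractions must be nonnegative")
  if (n_families < 1 || n_assayed < 2 || n_probes < 1)
    stop("configuration error: counts must be positive")
  if (family_size_range[1] < 3 || family_size_range[2] < family_size_range[1])
    stop("configuration error: invalid family size range")
  for (h in c(h2_ic_imatinib, h2_ic_omacetaxine))
    if (h < 0 || h >= 1) stop("configuration error: h2 must be in [0, 1)")
  structure(cfg, class = "sim_config")
}

#' Simulate the study pedigrees
#'
#' Builds `n_families` pedigrees of sizes in `family_size_range` (sizes drawn
#' with weight toward the small end so the cohort lands near the study's ~110
#' members). Most families are nuclear (two founders plus sibs); every fourth
#' family is three-generation (grandparent couple, two married sibs, their
#' children) so the assayed subset contains first-cousin = third-degree pairs.
#' Exactly one MZ pair is inserted among the sibs of the first family. The
#' assayed subset (default 55) is drawn from descendants with the MZ pair and
#' at least one cousin pair forced in.
#'
#' @param config a [sim_config()].
#' @return list with `pedigree` (class [pedigree]) and `assayed_ids`.
#' @export
simulate_pedigrees <- function(config = sim_config()) {
  set.seed(config$seed)
  lo <- config$family_size_range[1]
  hi <- config$family_size_range[2]
  draw_size <- function(avail) {
    wt <- rev(seq_along(avail))^3           # weight toward small families
    avail[sample.int(length(avail), 1, prob = wt)]
  }
  rows <- list()
  cousin_pool <- character(0)
  sib_pool <- character(0)
  mz_ids <- character(0)
  for (f in seq_len(config$n_families)) {
    fam <- sprintf("F%02d", f)
    # every fourth family is three-generation (needs >= 8 members: grandparent
    # couple, two married sibs, their children = first cousins)
    three_gen <- (f %% 4 == 0) && hi >= 8
    size <- if (three_gen) draw_size(max(lo, 8):hi) else draw_size(lo:hi)
    id <- function(k) sprintf("%s_I%02d", fam, k)
    if (three_gen) {
      # grandparents (1,2); their children (3,4); spouses (5,6); grandchildren
      n_gc <- size - 6
      gc_parents <- rep(list(c(3L, 5L), c(4L, 6L)), length.out = n_gc)
      fa <- c(NA, NA, 1L, 1L, NA, NA, vapply(gc_parents, `[`, 1L, 1))
      mo <- c(NA, NA, 2L, 2L, NA, NA, vapply(gc_parents, `[`, 2L, 2))
      sex <- c(1L, 2L, 1L, 1L, 2L, 2L,
               sample(1:2, n_gc, replace = TRUE))
      cousin_pool <- c(cousin_pool, id(6 + seq_len(n_gc)))
    } else {
      n_kids <- size - 2
      fa <- c(NA, NA, rep(1L, n_kids))
      mo <- c(NA, NA, rep(2L, n_kids))
      sex <- c(1L, 2L, sample(1:2, n_kids, replace = TRUE))
      sib_pool <- c(sib_pool, id(2 + seq_len(n_kids)))
    }
    mz <- rep(NA_character_, size)
    if (f == 1 && !three_gen) {            # one identical sib pair in family 1
      mz[3:4] <- "MZ1"
      sex[4] <- sex[3]
      mz_ids <- id(3:4)
    }
    rows[[f]] <- data.frame(
      family_id = fam,
      individual_id = id(seq_len(size)),
      father_id = ifelse(is.na(fa), NA, id(fa)),
      mother_id = ifelse(is.na(mo), NA, id(mo)),
      sex = sex,
      age = round(stats::runif(size, 20, 70), 1),
      mz_group = mz)
  }
  df <- do.call(rbind, rows)
  # MZ twins share age
  if (length(mz_ids) == 2)
    df$age[df$individual_id == mz_ids[2]] <- df$age[df$individual_id == mz_ids[1]]
  ped <- pedigree(df)

  pool <- c(sib_pool, cousin_pool)
  forced <- c(mz_ids, utils::head(cousin_pool, 2))
  n_extra <- config$n_assayed - length(forced)
  if (n_extra < 0 || n_extra > length(setdiff(pool, forced)))
    stop("configuration error: n_assayed infeasible for this pedigree set")
  assayed <- c(forced, sample(setdiff(pool, forced), n_extra))
  list(pedigree = ped, assayed_ids = assayed)
}

#' Simulate a polygenic trait on a relatedness structure
#'
#' `y = mean + X beta + g + e` with `g ~ MVN(0, h2 total_var 2Phi)` (drawn via
#' the eigen square root of 2 Phi) and `e ~ N(0, (1 - h2) total_var I)`.
#' Consumes the current RNG stream (seed the caller).
#'
#' @param K a `kinship_matrix` or [kinship_eigen()].
#' @param h2 true heritability in `[0, 1)`.
#' @param mean trait mean.
#' @param total_var total trait variance.
#' @param X,beta optional covariate design and effects.
#' @return list with `values` (named by individual id) and `truth`
#'   (list of generating parameters).
#' @export
simulate_polygenic_trait <- function(K, h2, mean = 0, total_var = 1,
                                     X = NULL, beta = NULL) {
  if (h2 < 0 || h2 >= 1) stop("argument error: h2 must be in [0, 1)")
  ke <- kinship_eigen(K)
  n <- length(ke$values)
  g <- if (h2 > 0)
    ke$vectors %*% (sqrt(h2 * total_var * ke$values) * stats::rnorm(n))
  else rep(0, n)
  e <- stats::rnorm(n, sd = sqrt((1 - h2) * total_var))
  y <- mean + drop(g) + e
  if (!is.null(X)) y <- y + drop(as.matrix(X) %*% beta)
  names(y) <- ke$ids
  list(values = y, truth = list(h2 = h2, mean = mean, total_var = total_var))
}

# Invert the viability equation: abs570 of a test well at fixed abs600 = 0.4
# such that percent_viability() returns v against untreated (0.8, 0.4).
abs570_for_viability <- function(v) {
  den <- .AB_C570 * 0.8 - .AB_C600 * 0.4
  (v / 100 * den + .AB_C600 * 0.4) / .AB_C570
}

#' Simulate plate absorbances from true dose-response curves
#'
#' Viability at each grid dose follows a 4PL curve (bottom 0, top 100, the
#' line's true log IC50, common Hill slope); replicate viabilities are
#' perturbed by Gaussian noise (`plate_noise_sd`, percent points, clipped
#' below at 1) and converted back to well absorbances by inverting the
#' viability equation at fixed `abs600 = 0.4` against untreated wells
#' `(0.8, 0.4)`. Consumes the current RNG stream.
#'
#' @param line_ids cell-line identifiers.
#' @param true_log_ic50 per-line true log10 IC50 (molar).
#' @param drug drug label written to the records.
#' @param dose_grid doses (molar).
#' @param hill Hill slope.
#' @param noise_sd replicate viability noise SD (percent points).
#' @param n_replicates wells per dose (default 3).
#' @return data.frame of plate records (treated wells plus untreated
#'   `drug = "none"` wells per line).
#' @export
simulate_plate_data <- function(line_ids, true_log_ic50, drug, dose_grid,
                                hill = 1, noise_sd = 2, n_replicates = 3) {
  if (length(line_ids) != length(true_log_ic50))
    stop("argument error: one true log IC50 per line required")
  out <- list()
  for (i in seq_along(line_ids)) {
    v_true <- four_pl(log10(dose_grid), 0, 100, true_log_ic50[i], hill)
    for (rep_i in seq_len(n_replicates)) {
      v <- pmax(v_true + stats::rnorm(length(dose_grid), sd = noise_sd), 1)
      out[[length(out) + 1]] <- data.frame(
        line_id = line_ids[i], drug = drug, dose_molar = dose_grid,
        replicate = rep_i, abs570 = abs570_for_viability(v), abs600 = 0.4)
      u <- pmax(100 + stats::rnorm(1, sd = noise_sd), 1)
      out[[length(out) + 1]] <- data.frame(
        line_id = line_ids[i], drug = "none", dose_molar = 0,
        replicate = rep_i, abs570 = abs570_for_viability(u), abs600 = 0.4)
    }
  }
  do.call(rbind, out)
}

#' Simulate an expression matrix with planted cluster structure
#'
#' Each probe is null (true mean iFC = oFC = 0) or belongs to one of four
#' clusters whose true (iFC, oFC) means are the configured centers plus
#' per-probe scatter (`fc_noise_sd`). Per line, the fold change adds a
#' polygenic deviation on 2 Phi (per-probe heritability drawn from
#' `h2r_range`) and iid noise, totalling `fc_line_sd^2`. Untreated intensities
#' are lognormal per probe/line; treated intensities are `untreated * 2^FC`.
#' Consumes the current RNG stream.
#'
#' @param K `kinship_matrix`/[kinship_eigen()] over the assayed lines.
#' @param config a [sim_config()].
#' @return list with `expression` (probes x samples matrix, columns
#'   `line:condition`), `truth` (data.frame: probe, cluster, true mean
#'   iFC/oFC, h2r per drug), and `fc_true` (list of probes x lines matrices).
#' @export
simulate_expression <- function(K, config = sim_config()) {
  ke <- kinship_eigen(K)
  lines <- ke$ids
  n <- length(lines)
  np <- config$n_probes
  probes <- sprintf("P%05d", seq_len(np))
  cl <- sample(0:4, np, replace = TRUE,
               prob = c(config$null_fraction, config$cluster_fractions))
  centers <- rbind(c(0, 0), config$cluster_centers)
  mu <- centers[cl + 1, , drop = FALSE] +
    matrix(stats::rnorm(2 * np, sd = config$fc_noise_sd), np, 2) *
    (cl > 0)                              # null probes have exact zero mean
  h2r_i <- stats::runif(np, config$h2r_range[1], config$h2r_range[2])
  h2r_o <- stats::runif(np, config$h2r_range[1], config$h2r_range[2])

  line_fc <- function(mu_p, h2r) {
    # polygenic + iid residual around the probe mean, total var fc_line_sd^2
    sv <- config$fc_line_sd^2
    g <- ke$vectors %*% (sqrt(h2r * sv * ke$values) * stats::rnorm(n))
    mu_p + drop(g) + stats::rnorm(n, sd = sqrt((1 - h2r) * sv))
  }
  ifc <- t(vapply(seq_len(np), function(p) line_fc(mu[p, 1], h2r_i[p]),
                  numeric(n)))
  ofc <- t(vapply(seq_len(np), function(p) line_fc(mu[p, 2], h2r_o[p]),
                  numeric(n)))

  base <- matrix(2^(stats::rnorm(np, 7, 1.5) +
                    matrix(stats::rnorm(np * n, 0, 0.2), np, n)), np, n)
  expr <- cbind(base, base * 2^ifc, base * 2^ofc)
  dimnames(expr) <- list(probes,
                         c(paste0(lines, ":untreated"),
                           paste0(lines, ":imatinib"),
                           paste0(lines, ":omacetaxine")))
  truth <- data.frame(probe_id = probes, cluster = cl,
                      mean_ifc = mu[, 1], mean_ofc = mu[, 2],
                      h2r_imatinib = h2r_i, h2r_omacetaxine = h2r_o)
  dimnames(ifc) <- dimnames(ofc) <- list(probes, lines)
  list(expression = expr, truth = truth, fc_true = list(ifc = ifc, ofc = ofc))
}

#' Simulate qPCR CT triplicates consistent with fold-change truth
#'
#' Target CT in the untreated condition is the gene baseline; the treated CT
#' is baseline minus the true log2 fold change (perfect doubling). The
#' reference gene's CT is constant across conditions. Triplicates get Gaussian
#' noise (`ct_noise_sd` cycles). Consumes the current RNG stream.
#'
#' @param fc_list named list of genes x lines matrices of true log2 fold
#'   changes, one element per treated condition (e.g. `imatinib`,
#'   `omacetaxine`).
#' @param reference_gene reference gene name.
#' @param baseline_ct named per-gene baseline CT (default 25 for all).
#' @param reference_ct reference gene CT (default 20).
#' @param noise_sd replicate noise SD in cycles.
#' @return CT table data.frame (`sample_id`, `gene`, `condition`,
#'   `ct1..ct3`).
#' @export
simulate_ct <- function(fc_list, reference_gene = "HPRT1",
                        baseline_ct = NULL, reference_ct = 20,
                        noise_sd = 0.1) {
  genes <- rownames(fc_list[[1]])
  lines <- colnames(fc_list[[1]])
  if (is.null(baseline_ct))
    baseline_ct <- stats::setNames(rep(25, length(genes)), genes)
  rows <- list()
  emit <- function(sample, gene, condition, ct_mean) {
    cts <- ct_mean + stats::rnorm(3, sd = noise_sd)
    rows[[length(rows) + 1]] <<- data.frame(
      sample_id = sample, gene = gene, condition = condition,
      ct1 = cts[1], ct2 = cts[2], ct3 = cts[3])
  }
  for (l in lines) {
    emit(l, reference_gene, "untreated", reference_ct)
    for (cond in names(fc_list)) emit(l, reference_gene, cond, reference_ct)
    for (g in genes) {
      emit(l, g, "untreated", baseline_ct[g])
      for (cond in names(fc_list))
        emit(l, g, cond, baseline_ct[g] - fc_list[[cond]][g, l])
    }
  }
  do.call(rbind, rows)
}

#' Simulate the complete study dataset
#'
#' Orchestrates all generators under one seed: pedigrees, heritable log-IC50
#' traits per drug (imatinib heritable, omacetaxine not, by default), plate
#' absorbances on the study dose grids, the planted-cluster expression matrix
#' over the assayed subset, and CT tables for a 5-gene qPCR panel drawn from
#' the planted clusters.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `pedigree`, `assayed_ids`, `kinship` (full
#'   cohort), `kinship_assayed`, `true_log_ic50`, `plates`, `expression`,
#'   `expression_truth`, `fc_true`, `ct`, `qpcr_genes`.
#' @export
simulate_study <- function(config = sim_config()) {
  sim <- simulate_pedigrees(config)
  K_all <- kinship_matrix(sim$pedigree)
  K_assay <- kinship_matrix(sim$pedigree, sim$assayed_ids)

  true_ic <- list()
  plates <- list()
  for (drug in c("imatinib", "omacetaxine")) {
    h2 <- if (drug == "imatinib") config$h2_ic_imatinib else config$h2_ic_omacetaxine
    tr <- simulate_polygenic_trait(K_all, h2,
                                   mean = config$mean_log_ic50[[drug]],
                                   total_var = config$sd_log_ic50^2)
    true_ic[[drug]] <- tr$values
    plates[[drug]] <- simulate_plate_data(
      K_all$ids, tr$values, drug, config$dose_grids[[drug]],
      hill = config$hill, noise_sd = config$plate_noise_sd)
  }
  plates <- unique(do.call(rbind, plates))

  ex <- simulate_expression(K_assay, config)
  planted <- which(ex$truth$cluster > 0)
  qpcr_probes <- ex$truth$probe_id[utils::head(planted, 5)]
  ct <- simulate_ct(list(imatinib = ex$fc_true$ifc[qpcr_probes, , drop = FALSE],
                         omacetaxine = ex$fc_true$ofc[qpcr_probes, , drop = FALSE]),
                    noise_sd = config$ct_noise_sd)
  list(config = config, pedigree = sim$pedigree,
       assayed_ids = sim$assayed_ids, kinship = K_all,
       kinship_assayed = K_assay, true_log_ic50 = true_ic, plates = plates,
       expression = ex$expression, expression_truth = ex$truth,
       fc_true = ex$fc_true, ct = ct, qpcr_genes = qpcr_probes)
}
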