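test_that("simulation config validates its invariants", {
  cfg <- sim_config()
  expect_equal(cfg$n_families, 17)
  expect_equal(cfg$n_assayed, 55)
  expect_equal(sum(cfg$cluster_fractions) + cfg$null_fraction, 1)
  expect_error(sim_config(cluster_fractions = c(0.5, 0.2, 0.2, 0.2)),
               "configuration error")
  expect_error(sim_config(h2_ic_imatinib = 1.2), "configuration error")
  expect_error(sim_config(n_families = 0), "configuration error")
})

test_that("pedigree generator reproduces the study family structure", {
  cfg <- sim_config(seed = 17)
  sim <- simulate_pedigrees(cfg)
  ped <- sim$pedigree
  fams <- table(ped$family_id)
  expect_equal(length(fams), 17)
  expect_true(all(fams >= 6 & fams <= 10))
  expect_true(sum(fams) >= 102 && sum(fams) <= 170)
  expect_equal(length(sim$assayed_ids), 55)
  # assayed subset carries sibs, third-degree pairs and exactly one MZ pair
  phi <- kinship_matrix(ped, sim$assayed_ids)$phi
  off <- phi[upper.tri(phi)]
  expect_gt(sum(off == 0.25), 0)      # sib (first-degree) pairs
  expect_gt(sum(off == 0.0625), 0)    # first cousins (third-degree)
  expect_equal(sum(off == 0.5), 1)    # exactly one MZ pair
  expect_equal(classify_relationship(
    ped, sim$assayed_ids[1], sim$assayed_ids[2]), "mz")
  # determinism
  sim2 <- simulate_pedigrees(cfg)
  expect_identical(as.data.frame(sim$pedigree), as.data.frame(sim2$pedigree))
  expect_identical(sim$assayed_ids, sim2$assayed_ids)
  # single small family
  s1 <- simulate_pedigrees(sim_config(n_families = 1,
                                      family_size_range = c(6, 6),
                                      n_assayed = 4))
  expect_equal(nrow(s1$pedigree), 6)
})

test_that("polygenic trait generator honours the kinship covariance", {
  cfg <- sim_config(seed = 18)
  sim <- simulate_pedigrees(cfg)
  K <- kinship_eigen(kinship_matrix(sim$pedigree))
  set.seed(18)
  y0 <- simulate_polygenic_trait(K, 0)$values
  expect_equal(length(y0), length(K$ids))
  # MZ pairs correlate more than sib pairs across replicates at high h2
  ped <- sim$pedigree
  mz <- ped$individual_id[!is.na(ped$mz_group)]
  sibs <- c(grep("F02_I03", K$ids, value = TRUE), grep("F02_I04", K$ids, value = TRUE))
  set.seed(19)
  draws <- replicate(400, simulate_polygenic_trait(K, 0.8)$values)
  c_mz <- cor(draws[match(mz[1], K$ids), ], draws[match(mz[2], K$ids), ])
  c_sib <- cor(draws[match(sibs[1], K$ids), ], draws[match(sibs[2], K$ids), ])
  expect_gt(c_mz, c_sib)
  expect_error(simulate_polygenic_trait(K, 1.5), "argument error")
})

test_that("plate generator round-trips through the viability pipeline", {
  cfg <- sim_config(seed = 20)
  set.seed(20)
  # zero noise: exact recovery of the true IC20
  plates <- simulate_plate_data(c("L1", "L2"), c(-4.2, -4.6), "imatinib",
                                cfg$dose_grids$imatinib, noise_sd = 0)
  vp <- average_replicates(plates)
  v1 <- vp[vp$line_id == "L1", ]
  fit <- fit_4pl(v1$dose_molar, v1$viability)
  expect_equal(fit$log_ic50, -4.2, tolerance = 1e-6)
  expect_equal(log10(inhibitory_concentration(fit, 20)),
               -4.2 + log10(1 / 4), tolerance = 1e-6)
  # determinism under a fixed stream
  set.seed(21)
  p1 <- simulate_plate_data("L1", -4.2, "imatinib", cfg$dose_grids$imatinib)
  set.seed(21)
  p2 <- simulate_plate_data("L1", -4.2, "imatinib", cfg$dose_grids$imatinib)
  expect_identical(p1, p2)
  # noisy IC20 recovery within 0.1 log10 units in the median
  set.seed(22)
  truths <- runif(60, -4.8, -4.1)
  plates_n <- simulate_plate_data(sprintf("L%02d", 1:60), truths, "imatinib",
                                  cfg$dose_grids$imatinib, noise_sd = 2)
  vpn <- average_replicates(plates_n)
  err <- vapply(1:60, function(i) {
    vi <- vpn[vpn$line_id == sprintf("L%02d", i), ]
    f <- fit_4pl(vi$dose_molar, vi$viability)
    log10(inhibitory_concentration(f, 20)) - (truths[i] + log10(1 / 4))
  }, numeric(1))
  expect_lt(median(abs(err)), 0.1)
})

test_that("expression generator plants the advertised structure", {
  cfg <- sim_config(seed = 23, n_probes = 600)
  sim <- simulate_pedigrees(cfg)
  K <- kinship_matrix(sim$pedigree, sim$assayed_ids)
  set.seed(23)
  ex <- simulate_expression(K, cfg)
  expect_equal(dim(ex$expression), c(600, 3 * 55))
  expect_equal(sort(unique(ex$truth$cluster)), 0:4)
  # null probes have exactly zero planted means
  expect_true(all(ex$truth$mean_ifc[ex$truth$cluster == 0] == 0))
  # recomputed fold changes match the generated ones (floor never binding)
  fc <- fold_change_table(ex$expression)
  expect_equal(fc$ifc, ex$fc_true$ifc, tolerance = 1e-8)
  expect_equal(fc$ofc, ex$fc_true$ofc, tolerance = 1e-8)
  # planted per-line FC centers on the probe mean
  planted <- which(ex$truth$cluster > 0)
  dev <- rowMeans(ex$fc_true$ifc[planted, , drop = FALSE]) -
    ex$truth$mean_ifc[planted]
  expect_lt(max(abs(dev)), 4 * cfg$fc_line_sd / sqrt(55) + 0.1)
})

test_that("whole-study simulation is reproducible and self-consistent", {
  cfg <- sim_config(seed = 24, n_probes = 60)
  st1 <- simulate_study(cfg)
  st2 <- simulate_study(cfg)
  expect_identical(st1$plates, st2$plates)
  expect_identical(st1$expression, st2$expression)
  expect_identical(st1$ct, st2$ct)
  expect_equal(length(st1$true_log_ic50$imatinib), nrow(st1$pedigree))
  expect_setequal(colnames(st1$fc_true$ifc), st1$assayed_ids)
  expect_equal(length(st1$qpcr_genes), 5)
})
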