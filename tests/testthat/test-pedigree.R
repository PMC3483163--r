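test_that("pedigree files round-trip and validate structure", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(pedigree(trio_df()), path)
  ped <- load_pedigree(path)
  expect_s3_class(ped, "pedigree")
  expect_setequal(founders(ped), c("F", "M"))
  expect_equal(nrow(ped) - length(founders(ped)), 1)

  bad <- trio_df(); bad$father_id[3] <- "C"
  expect_error(pedigree(bad), "own parent")
  cyc <- trio_df(); cyc$father_id[1] <- "C"   # F's father is its grandchild
  expect_error(pedigree(cyc), "cycle")
  dup <- rbind(trio_df(), trio_df()[3, ])
  expect_error(pedigree(dup), "duplicated")
  orphan <- trio_df(); orphan$mother_id[3] <- "X"
  expect_error(pedigree(orphan), "unresolved")
})

test_that("kinship recursion reproduces the standard identity coefficients", {
  ped <- pedigree(cousin_df())
  expect_equal(kinship_coefficient(ped, "gf", "gf"), 0.5)   # non-inbred self
  expect_equal(kinship_coefficient(ped, "s1", "s2"), 0.25)  # full sibs
  expect_equal(kinship_coefficient(ped, "c1", "c2"), 1 / 16) # first cousins
  expect_equal(kinship_coefficient(ped, "gf", "w1"), 0)     # unrelated founders
  expect_equal(kinship_coefficient(ped, "s1", "c1"), 0.25)  # parent-offspring
  expect_equal(kinship_coefficient(ped, "s1", "c2"), 0.125) # uncle-nephew
  expect_error(kinship_coefficient(ped, "s1", "nope"), "lookup error")
})

test_that("MZ twins are genetically identical to the recursion", {
  df <- cousin_df()
  df$mz_group <- NA_character_
  df$mz_group[df$individual_id %in% c("s1", "s2")] <- "Z"
  ped <- pedigree(df)
  expect_equal(kinship_coefficient(ped, "s1", "s2"), 0.5)
  # children of MZ twins are genetic half-sibs-on-one-side: like parent/child
  # through either twin
  expect_equal(kinship_coefficient(ped, "c1", "s2"), 0.25)
  # the cousins become genetic half sibs: Phi = 1/8
  expect_equal(kinship_coefficient(ped, "c1", "c2"), 0.125)
  expect_equal(classify_relationship(ped, "s1", "s2"), "mz")

  # mz members must share parents
  bad <- cousin_df(); bad$mz_group <- NA_character_
  bad$mz_group[bad$individual_id %in% c("s1", "w1")] <- "Z"
  expect_error(pedigree(bad), "share both parents")
})

test_that("recursive kinship agrees with gene-dropping Monte Carlo", {
  set.seed(42)
  ped <- pedigree(cousin_df(4))   # 10 members, three generations
  pairs <- list(c("s1", "s2"), c("c1", "c2"), c("s1", "c1"), c("gf", "c1"))
  for (pr in pairs) {
    mc <- gene_drop_phi(ped, pr[1], pr[2], n_drops = 2e5)
    expect_lt(abs(kinship_coefficient(ped, pr[1], pr[2]) - mc$phi),
              3 * mc$se + 1e-12)
  }
})

test_that("relatedness matrix is PSD, block-diagonal, founder-stable", {
  df <- rbind(cousin_df(), trio_df())
  ped <- pedigree(df)
  K <- kinship_matrix(ped)
  expect_true(isSymmetric(K$relatedness))
  expect_equal(K$relatedness, 2 * K$phi)
  expect_gte(min(eigen(K$relatedness, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
  # cross-family block exactly zero
  a <- K$ids[startsWith(K$ids, "c") | K$ids %in% c("gf", "gm", "s1", "s2", "w1", "w2")]
  b <- setdiff(K$ids, a)
  expect_true(all(K$relatedness[a, b] == 0))
  # adding an unrelated founder leaves existing entries unchanged
  df2 <- rbind(df, data.frame(family_id = "T", individual_id = "X",
                              father_id = NA, mother_id = NA, sex = 1))
  K2 <- kinship_matrix(pedigree(df2), K$ids)
  expect_equal(K2$relatedness, K$relatedness)
  expect_error(kinship_matrix(ped, character(0)), "empty")
})

test_that("relationship classification follows the kinship bands", {
  ped <- pedigree(cousin_df())
  expect_equal(classify_relationship(ped, "s1", "s1"), "self")
  expect_equal(classify_relationship(ped, "s1", "s2"), "first-degree")
  expect_equal(classify_relationship(ped, "s1", "c2"), "second-degree")
  expect_equal(classify_relationship(ped, "c1", "c2"), "third-degree")
  expect_equal(classify_relationship(ped, "gf", "w1"), "unrelated")
  # inbred configuration off the standard bands: child of a sib mating has
  # Phi = 3/8 with each parent
  inb <- data.frame(family_id = "I",
                    individual_id = c("f", "m", "a", "b", "k"),
                    father_id = c(NA, NA, "f", "f", "a"),
                    mother_id = c(NA, NA, "m", "m", "b"),
                    sex = c(1, 2, 1, 2, 1))
  ped_i <- pedigree(inb)
  expect_equal(kinship_coefficient(ped_i, "k", "a"), 0.375)
  expect_equal(classify_relationship(ped_i, "k", "a"), "other")
})
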