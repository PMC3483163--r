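test_that("inverse normal transform maps ranks to Blom normal quantiles", {
  y <- c(3.2, -1.0, 7.5)
  z <- inverse_normal_transform(y)
  expect_equal(z[1], 0)                               # middle value -> median
  expect_equal(z[2], qnorm((1 - 3/8) / (3 + 1/4)))    # = qnorm(0.625/3.25)
  expect_equal(z[2], -0.8694, tolerance = 1e-4)
  expect_true(all(order(z) == order(y)))              # monotone
  # ties share the average rank
  z4 <- inverse_normal_transform(c(1, 1, 2, 3))
  expect_equal(z4[1], z4[2])
  expect_error(inverse_normal_transform(rep(2, 5)), "degenerate")
})

test_that("inverse normal output is indistinguishable from normal", {
  set.seed(11)
  ok <- replicate(40, {
    x <- rexp(100)^2   # aggressively non-normal input
    shapiro.test(inverse_normal_transform(x))$p.value > 0.01
  })
  expect_gte(mean(ok), 0.95)
})

test_that("covariate matrix has the fixed five-column design", {
  X <- covariate_matrix(age = c(40, 40, 0), sex = c(1, 0, 1))
  expect_equal(colnames(X), c("age", "sex", "age_sex", "age2", "age2_sex"))
  expect_equal(unname(X[1, ]), c(40, 1, 40, 1600, 1600))
  expect_equal(unname(X[2, ]), c(40, 0, 0, 1600, 0))
  expect_equal(unname(X[3, ]), c(0, 1, 0, 0, 0))
  # pedigree 1/2 coding converts to 1 = male, 0 = female
  X2 <- covariate_matrix(age = c(40, 40), sex = c(1, 2))
  expect_equal(unname(X2[, "sex"]), c(1, 0))
  expect_warning(covariate_matrix(age = c(40, NA), sex = c(1, 1)), "dropped")
})

test_that("sporadic ML fit matches OLS closed forms", {
  set.seed(21)
  n <- 200
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  beta <- c(1.5, -0.7)
  y <- 2 + X %*% beta + rnorm(n)
  fit <- fit_sporadic(y, X)
  ols <- lm(y ~ X)
  expect_equal(unname(fit$beta), unname(coef(ols)[-1]), tolerance = 1e-8)
  expect_equal(fit$mean, unname(coef(ols)[1]), tolerance = 1e-8)
  expect_equal(fit$loglik, as.numeric(logLik(ols)), tolerance = 1e-6)
  expect_equal(fit$sigma2_g, 0)
  # null design: the mean is the sample mean
  y2 <- rnorm(50)
  expect_equal(fit_sporadic(y2)$mean, mean(y2), tolerance = 1e-10)
  expect_error(fit_sporadic(rep(0, 30)), "degenerate")
})

test_that("polygenic profile fit equals the dense MVN likelihood", {
  set.seed(31)
  for (rep_i in 1:50) {
    K <- random_small_kinship(30)
    n <- length(K$ids)
    y <- simulate_polygenic_trait(K, runif(1, 0, 0.8))$values
    X <- if (runif(1) < 0.5)
      cbind(age = runif(n, 20, 70), sex = rbinom(n, 1, 0.5))
    else NULL
    fit <- fit_polygenic(y, X, K)
    M <- if (is.null(X)) matrix(1, n, 1) else cbind(1, X)
    # same likelihood by an independent dense route at the fitted h2
    expect_equal(fit$loglik, dense_profile_ll(y, M, K$relatedness, fit$h2),
                 tolerance = 1e-6)
    # and no h2 on a fine dense grid beats it
    grid_ll <- vapply(seq(0, 0.99, by = 0.01), function(h)
      dense_profile_ll(y, M, K$relatedness, h), numeric(1))
    expect_lte(max(grid_ll), fit$loglik + 1e-6)
  }
})

test_that("polygenic fit nests the sporadic fit and flags identity kinship", {
  set.seed(41)
  K <- random_small_kinship(24)
  y <- simulate_polygenic_trait(K, 0.5)$values
  full <- fit_polygenic(y, K = K)
  con <- fit_sporadic(y)
  expect_gte(full$loglik, con$loglik - 1e-9)
  expect_true(full$h2 >= 0 && full$h2 < 1)
  expect_gte(full$sigma2_g, 0)
  expect_gt(full$sigma2_e, 0)
  # unrelated individuals: h2 not identifiable
  I <- structure(list(ids = paste0("u", 1:20), phi = diag(20) / 2,
                      relatedness = diag(20)), class = "kinship_matrix")
  expect_warning(fit_polygenic(rnorm(20), K = I), "identifiability")
  expect_error(fit_polygenic(rnorm(3), covariate_matrix(1:3 * 10, c(0, 1, 0)), K),
               "rank error|length")
})

test_that("LRT uses plain chi-square for interior, half mixture at boundary", {
  f <- function(ll) structure(list(loglik = ll), class = "vc_fit")
  expect_equal(lrt(f(-10), f(-10), boundary = TRUE)$p, 0.5)
  expect_equal(lrt(f(-8.07925), f(-10))$statistic, 3.8415)
  expect_equal(lrt(f(-8.07925), f(-10))$p, 0.05, tolerance = 1e-4)
  expect_equal(lrt(f(-8.07925), f(-10), boundary = TRUE)$p, 0.025,
               tolerance = 1e-4)
  expect_equal(lrt(f(-10), f(-10))$p, 1)
  expect_error(lrt(f(-11), f(-10)), "optimization-failure")
})

test_that("mean test reduces to the classical regression test without kinship", {
  set.seed(51)
  n <- 60
  fc <- rnorm(n, 0.4, 1)
  res <- mean_fc_test(fc, use_kinship = FALSE)
  # oracle: one-sample LRT for a normal mean has the same statistic
  ll1 <- sum(dnorm(fc, mean(fc), sqrt(mean((fc - mean(fc))^2)), log = TRUE))
  ll0 <- sum(dnorm(fc, 0, sqrt(mean(fc^2)), log = TRUE))
  expect_equal(res$statistic, 2 * (ll1 - ll0), tolerance = 1e-6)
  expect_equal(res$mean, mean(fc), tolerance = 1e-8)
  expect_error(mean_fc_test(rep(0, 20), use_kinship = FALSE), "degenerate")
  expect_error(mean_fc_test(fc, use_kinship = TRUE), "kinship matrix required")
})

test_that("mean test has power at the study scale", {
  set.seed(61)
  cfg <- sim_config(seed = 61, n_assayed = 55)
  sp <- simulate_pedigrees(cfg)
  K <- kinship_eigen(kinship_matrix(sp$pedigree, sp$assayed_ids))
  n <- length(K$values)
  hits <- replicate(100, {
    y <- rnorm(n, mean = 0.5, sd = 1)
    mean_fc_test(y, K = K)$p < 0.05
  })
  expect_gt(mean(hits), 0.9)
})

test_that("FC-SDR association recovers the coefficient and matches OLS when h2=0", {
  set.seed(71)
  cfg <- sim_config(seed = 71)
  sp <- simulate_pedigrees(cfg)
  K <- kinship_eigen(kinship_matrix(sp$pedigree, sp$assayed_ids))
  n <- length(K$values)
  # recovery: sdr = 0.8 fc + polygenic noise
  coefs <- replicate(40, {
    fc <- rnorm(n)
    y <- 0.8 * fc + simulate_polygenic_trait(K, 0.4, total_var = 0.5)$values
    fc_sdr_association(y, fc, K = K)$coefficient
  })
  expect_equal(mean(coefs), 0.8, tolerance = 0.05)
  # no-kinship limit: iid response, p close to the OLS t-test p
  set.seed(72)
  fc <- rnorm(n)
  y <- 0.3 * fc + rnorm(n)
  a <- fc_sdr_association(y, fc, K = K)
  ols_p <- summary(lm(y ~ fc))$coefficients["fc", 4]
  expect_equal(a$p, ols_p, tolerance = 0.1 * ols_p + 0.01)
  expect_error(fc_sdr_association(y, rep(1, n), K = K), "collinearity")
})

test_that("heritability test recovers truth and behaves at the null", {
  set.seed(81)
  cfg <- sim_config(seed = 81)
  sp <- simulate_pedigrees(cfg)
  K <- kinship_eigen(kinship_matrix(sp$pedigree))
  h <- replicate(60, heritability_test(
    simulate_polygenic_trait(K, 0.6)$values, K = K)$h2)
  expect_lt(abs(mean(h) - 0.6), 0.08)
  # family-constant trait pushes h2 to the upper clamp
  fam <- sub("_.*", "", K$ids)
  y_fam <- rnorm(length(unique(fam)))[match(fam, unique(fam))] +
    rnorm(length(fam), sd = 1e-3)
  expect_gt(heritability_test(y_fam, K = K)$h2, 0.9)
})
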