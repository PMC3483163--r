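# brute-force BH step-up, independent of p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n); q[o] <- pmin(q_sorted, 1)
  q
}

test_that("BH q-values follow the step-up rule", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  res <- bh_qvalues(p)
  expect_equal(res$q, rep(0.04, 4))
  expect_equal(bh_qvalues(0.3)$q, 0.3)
  expect_equal(bh_qvalues(rep(1, 3))$q, rep(1, 3))
  set.seed(8)
  pr <- runif(500)^2
  expect_equal(bh_qvalues(pr)$q, bh_oracle(pr))
  # q monotone non-decreasing in p
  r <- bh_qvalues(pr)
  expect_true(all(diff(r$q[order(r$p)]) >= -1e-15))
  expect_error(bh_qvalues(c(0.5, 0)), "argument")
})

test_that("k-means separates well-separated pairs and is seed-deterministic", {
  pts <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10.1, 10))
  rep1 <- kmeans_fc(pts, k = 2, seed = 3, restarts = 10)
  expect_equal(sort(rep1$sizes), c(2, 2))
  cents <- rep1$centers[order(rep1$centers[, 1]), ]
  expect_equal(cents, rbind(c(0.05, 0), c(10.05, 10)))
  rep2 <- kmeans_fc(pts, k = 2, seed = 3, restarts = 10)
  expect_identical(rep1$assignment, rep2$assignment)
  # k = n: every point its own cluster, zero WCSS
  repn <- kmeans_fc(pts, k = 4, seed = 1, restarts = 5)
  expect_equal(sort(repn$sizes), rep(1, 4))
  expect_equal(repn$wcss, 0)
  expect_error(kmeans_fc(pts, k = 0), "argument")
  expect_error(kmeans_fc(pts, k = 9), "argument")
})

test_that("cluster relabelling matches reference centers", {
  set.seed(9)
  ref <- rbind(c(-0.02, 0.26), c(-0.08, -0.35), c(0.36, 0.10), c(0.13, 0.50))
  truth <- sample(1:4, 400, replace = TRUE)
  pts <- ref[truth, ] + matrix(rnorm(800, sd = 0.05), 400, 2)
  rep4 <- match_clusters(kmeans_fc(pts, k = 4, seed = 2), ref)
  expect_gt(mean(rep4$assignment == truth), 0.95)
  for (cl in 1:4)
    expect_lt(sum((rep4$centers[cl, ] - ref[cl, ])^2), 0.01)
  cs <- cluster_summary(rep4, pts)
  expect_equal(cs$size, rep4$sizes)
  expect_equal(sum(cs$size), 400)
  expect_equal(cs$percent, 100 * rep4$sizes / 400)
  # planted means recovered within 2 SE per coordinate
  for (cl in 1:4) {
    se <- 0.05 / sqrt(cs$size[cl])
    expect_lt(abs(cs$mean_ifc[cl] - ref[cl, 1]), 3 * se + 0.01)
    expect_lt(abs(cs$mean_ofc[cl] - ref[cl, 2]), 3 * se + 0.01)
  }
})

test_that("significance-set overlap counts against the universe", {
  uni <- paste0("p", 1:1000)
  expect_equal(significant_overlap(uni[1:10], uni[11:20], uni)$count, 0)
  ov <- significant_overlap(uni[1:10], uni[1:10], uni)
  expect_equal(ov$count, 10)
  expect_equal(ov$fraction, 0.01)
  # independence: expected overlap |A||B|/N
  set.seed(10)
  counts <- replicate(200, {
    significant_overlap(sample(uni, 100), sample(uni, 50), uni)$count
  })
  expect_equal(mean(counts), 100 * 50 / 1000, tolerance = 0.1)
  expect_error(significant_overlap(c("x"), uni[1:3], uni), "subsets")
})

test_that("confidence ellipses scale with the chi-square quantile", {
  set.seed(12)
  pts <- matrix(rnorm(2e4), ncol = 2)
  e <- confidence_ellipse(pts, 0.95)
  expect_equal(unname(e$semi_axes), rep(sqrt(qchisq(0.95, 2)), 2),
               tolerance = 0.05)
  expect_equal(unname(e$center), c(0, 0), tolerance = 0.05)
  # Monte-Carlo coverage near the nominal level
  inside <- mahalanobis(pts, e$center, e$cov) <= qchisq(0.95, 2)
  expect_equal(mean(inside), 0.95, tolerance = 0.01)
  # boundary points satisfy the ellipse equation
  bp <- ellipse_points(e, 50)
  d <- mahalanobis(bp, e$center, e$cov)
  expect_equal(d, rep(qchisq(0.95, 2), 50), tolerance = 1e-8)
  expect_error(confidence_ellipse(cbind(1:5, 2 * (1:5))), "degenerate")
  expect_error(confidence_ellipse(pts[1:2, ]), ">= 3")
})

test_that("Kruskal-Wallis matches the rank closed form", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  # H = 12/(n(n+1)) sum R_i^2/n_i - 3(n+1) with rank sums 6 and 15
  expect_equal(r$H, 12 / (6 * 7) * (36 / 3 + 225 / 3) - 3 * 7, tolerance = 1e-10)
  expect_equal(r$H, 3.857, tolerance = 1e-3)
  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$H, 0, tolerance = 1e-12)
  expect_warning(tied <- kruskal_wallis(list(c(2, 2), c(2, 2, 2))), "tied")
  expect_equal(tied$H, 0)
  expect_equal(tied$p, 1)
  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("proportion chi-square equals the squared z statistic", {
  r <- proportion_chi2(8, 100, 0.04)
  expect_equal(r$chi2, 4.1667, tolerance = 1e-4)
  expect_equal(r$p, 0.0412, tolerance = 1e-3)
  expect_equal(proportion_chi2(4, 100, 0.04)$chi2, 0)
  expect_equal(proportion_chi2(4, 100, 0.04)$p, 1)
  # doubling k and n doubles the statistic
  expect_equal(proportion_chi2(16, 200, 0.04)$chi2, 2 * r$chi2)
  # algebraic identity with the one-sample z for a proportion
  set.seed(13)
  for (i in 1:20) {
    n <- sample(50:500, 1); p0 <- runif(1, 0.05, 0.5)
    k <- rbinom(1, n, p0 * runif(1, 0.5, 1.5))
    z <- (k / n - p0) / sqrt(p0 * (1 - p0) / n)
    expect_equal(proportion_chi2(k, n, p0)$chi2, z^2, tolerance = 1e-10)
  }
  expect_warning(proportion_chi2(1, 10, 0.01), "small expected")
})
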