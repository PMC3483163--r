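# Maximum-likelihood variance-component (polygenic) models on pedigree
# relatedness, with boundary likelihood-ratio tests. This is the statistical
# core of the package: heritability of IC traits, kinship-corrected per-probe
# mean-fold-change tests, and fold-change / drug-sensitivity association.

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles via the Blom offset:
#' `qnorm((rank - 3/8) / (n + 1/4))`, ties receiving the average rank. The
#' output is monotone in the input and approximately standard normal.
#'
#' @param values numeric vector, `n >= 2`, not all equal.
#' @return transformed vector of the same length.
#' @export
inverse_normal_transform <- function(values) {
  if (length(values) < 2) stop("argument error: need n >= 2")
  if (diff(range(values)) == 0) stop("degenerate-trait error: all values identical")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 3/8) / (length(values) + 1/4))
}

#' Study covariate design matrix
#'
#' Fixed column order: age, sex, age x sex, age^2, age^2 x sex. Sex is coded
#' 0/1 (1 = male); ages are uncentered.
#'
#' @param age numeric vector of ages (years).
#' @param sex 0/1 vector (1 = male); pedigree codes 1/2 are converted.
#' @param ids optional rownames.
#' @return numeric matrix with columns
#'   `age, sex, age_sex, age2, age2_sex`. Rows with missing age/sex are
#'   dropped with a warning.
#' @export
covariate_matrix <- function(age, sex, ids = NULL) {
  if (all(sex %in% c(1, 2), na.rm = TRUE) && any(sex == 2, na.rm = TRUE))
    sex <- 2 - sex                      # pedigree coding -> 1 = male, 0 = female
  if (!all(sex %in% c(0, 1), na.rm = TRUE))
    stop("argument error: sex must be coded 0/1 (or pedigree 1/2)")
  X <- cbind(age = age, sex = sex, age_sex = age * sex,
             age2 = age^2, age2_sex = age^2 * sex)
  if (!is.null(ids)) rownames(X) <- ids
  drop <- apply(X, 1, anyNA)
  if (any(drop)) {
    warning(sum(drop), " individual(s) dropped for missing age/sex")
    X <- X[!drop, , drop = FALSE]
  }
  X
}

#' Precompute the eigendecomposition of a relatedness matrix
#'
#' The polygenic likelihood only needs the spectrum of 2 Phi; computing it
#' once and reusing it across thousands of probe fits is the standard trick.
#'
#' @param K a `kinship_matrix` (or bare symmetric relatedness matrix).
#' @return object of class `kinship_eigen`: list with `ids`, `values`,
#'   `vectors`.
#' @export
kinship_eigen <- function(K) {
  if (inherits(K, "kinship_eigen")) return(K)
  if (inherits(K, "kinship_matrix")) {
    rel <- K$relatedness; ids <- K$ids
  } else {
    rel <- as.matrix(K); ids <- rownames(rel)
  }
  e <- eigen(rel, symmetric = TRUE)
  structure(list(ids = ids, values = pmax(e$values, 0), vectors = e$vectors),
            class = "kinship_eigen")
}

# Profiled ML log-likelihood at a candidate heritability.
# ty, tM are the eigenvector-rotated response and design; d the eigenvalues
# of 2 Phi. For fixed h2 the covariance is sigma2 * diag(h2 d + 1 - h2), so
# beta is weighted LS and sigma2 = RSS_w / n in closed form.
vc_profile_ll <- function(h2, ty, tM, d, n) {
  w <- h2 * d + (1 - h2)
  if (ncol(tM) > 0) {
    tMw <- tM / w
    beta <- tryCatch(solve(crossprod(tM, tMw), crossprod(tMw, ty)),
                     error = function(e) stop("rank error: singular design"))
    r <- ty - tM %*% beta
  } else {
    beta <- matrix(numeric(0), 0, 1)
    r <- ty
  }
  rss <- sum(r^2 / w)
  sigma2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + sum(log(w)) + n)
  list(ll = ll, beta = drop(beta), sigma2 = sigma2)
}

vc_assemble <- function(h2, prof, model, n, mean_included, colnames_M) {
  beta <- prof$beta
  names(beta) <- colnames_M
  mean_est <- if (mean_included) unname(beta["(mean)"]) else 0
  covar_beta <- beta[setdiff(names(beta), "(mean)")]
  structure(list(mean = mean_est,
                 beta = covar_beta,
                 sigma2_g = h2 * prof$sigma2,
                 sigma2_e = (1 - h2) * prof$sigma2,
                 h2 = h2,
                 loglik = prof$ll,
                 model = model,
                 n = n),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("%s model (n=%d): h2 = %.3f, sigma2_g = %.4g, sigma2_e = %.4g, logLik = %.4f\n",
              x$model, x$n, x$h2, x$sigma2_g, x$sigma2_e, x$loglik))
  invisible(x)
}

build_design <- function(y, X, include_mean) {
  n <- length(y)
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("argument error: y and X lengths differ")
  } else {
    X <- matrix(numeric(0), n, 0)
  }
  M <- if (include_mean) cbind("(mean)" = rep(1, n), X) else X
  if (n <= ncol(M)) stop("rank error: n must exceed number of fixed effects")
  M
}

#' Fit the polygenic variance-component model by maximum likelihood
#'
#' Model: `y = mu + X beta + g + e` with `Cov(g) = sigma2_g * 2Phi` and
#' `Cov(e) = sigma2_e * I`. One eigendecomposition of 2 Phi reduces the
#' problem to a 1-D profile likelihood over `h2 = sigma2_g / (sigma2_g +
#' sigma2_e)`: for each candidate h2 the fixed effects and total variance have
#' closed-form ML solutions. The profile is maximized by a deterministic grid
#' over `[0, 1)` (uniform in the interior, geometrically refined toward the
#' upper boundary where the profile can spike when 2 Phi is singular) followed
#' by Brent refinement of the best brackets (tolerance 1e-8 on h2); h2 is
#' clamped to `[0, 1 - 1e-6]`.
#'
#' @param y numeric response aligned with `K`.
#' @param X optional covariate matrix (see [covariate_matrix()]).
#' @param K a `kinship_matrix` or precomputed [kinship_eigen()].
#' @param include_mean include a free intercept (the trait mean), default TRUE.
#' @return Object of class `vc_fit` with `mean`, `beta`, `sigma2_g`,
#'   `sigma2_e`, `h2`, `loglik`, `model = "polygenic"`, `n`.
#' @export
fit_polygenic <- function(y, X = NULL, K, include_mean = TRUE) {
  if (diff(range(y)) == 0) stop("degenerate-trait error: constant response")
  ke <- kinship_eigen(K)
  n <- length(y)
  if (n != length(ke$values))
    stop("argument error: y length does not match kinship matrix")
  M <- build_design(y, X, include_mean)
  d <- ke$values
  # Exact zero eigenvalues (duplicated genotypes: MZ twins) make the ML
  # profile degenerate near h2 = 1 whenever a covariate differs within the
  # pair; model twins as sharing all but a 5% sliver of the genetic deviation.
  d[d < 1e-8] <- 0.05
  if (max(abs(d - 1)) < 1e-10)
    warning("identifiability warning: relatedness is the identity; h2 is not identifiable")
  ty <- drop(crossprod(ke$vectors, y))
  tM <- crossprod(ke$vectors, M)
  colnames(tM) <- colnames(M)

  hmax <- 1 - 1e-6
  # The profile can be multimodal, with narrow spikes approaching h2 = 1 when
  # 2Phi is singular (MZ pairs), so the grid is uniform in the interior and
  # geometrically refined toward the upper boundary; Brent then polishes the
  # three best brackets.
  grid <- sort(unique(c(seq(0, 0.95, by = 0.05),
                        1 - 10^seq(-1.4, -5.5, length.out = 14), hmax)))
  f <- function(h) vc_profile_ll(h, ty, tM, d, n)$ll
  ll_grid <- vapply(grid, f, numeric(1))
  cand_h2 <- c(0, hmax)
  cand_ll <- c(ll_grid[1], ll_grid[length(grid)])
  for (i in utils::head(order(ll_grid, decreasing = TRUE), 3)) {
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(f, lower = lo, upper = hi, maximum = TRUE,
                           tol = 1e-8)
    cand_h2 <- c(cand_h2, grid[i], opt$maximum)
    cand_ll <- c(cand_ll, ll_grid[i], opt$objective)
  }
  h2 <- cand_h2[which.max(cand_ll)]
  if (h2 < 1e-7) h2 <- 0
  prof <- vc_profile_ll(h2, ty, tM, d, n)
  vc_assemble(h2, prof, "polygenic", n, include_mean, colnames(tM))
}

#' Fit the sporadic (independent-errors) model by maximum likelihood
#'
#' Fixed effects only: `y = m + X beta + e`, `e ~ N(0, sigma2_e I)`. This is
#' the polygenic model constrained to `sigma2_g = 0` and serves as the
#' constrained model in heritability LRTs.
#'
#' @inheritParams fit_polygenic
#' @return `vc_fit` with `sigma2_g = 0`, `model = "sporadic"`.
#' @export
fit_sporadic <- function(y, X = NULL, include_mean = TRUE) {
  if (diff(range(y)) == 0) stop("degenerate-trait error: constant response")
  n <- length(y)
  M <- build_design(y, X, include_mean)
  prof <- vc_profile_ll(0, y, M, rep(1, n), n)
  vc_assemble(0, prof, "sporadic", n, include_mean, colnames(M))
}

#' Likelihood-ratio test between nested variance-component fits
#'
#' `statistic = max(0, 2 (logLik_full - logLik_constrained))`. For interior
#' parameters (trait means, covariate coefficients) the null distribution is
#' chi-square with `df` degrees of freedom. For a variance component tested at
#' its boundary (`boundary = TRUE`, heritability tests) the null is the
#' half-half mixture of a point mass at 0 and chi-square(1), so `p = 0.5` when
#' the statistic is 0 and `p = 0.5 P(chisq_1 > s)` otherwise.
#'
#' @param full,constrained `vc_fit` objects, constrained nested in full.
#' @param boundary logical; use the boundary mixture null.
#' @param df degrees of freedom for the interior case (default 1).
#' @return list with `statistic`, `df`, `boundary`, `p`.
#' @export
lrt <- function(full, constrained, boundary = FALSE, df = 1) {
  delta <- 2 * (full$loglik - constrained$loglik)
  if (delta < -1e-6)
    stop("optimization-failure error: full model log-likelihood below constrained (",
         format(delta), ")")
  s <- max(0, delta)
  if (s < 1e-8) s <- 0   # numerically tied fits are an exact boundary tie
  p <- if (boundary) {
    if (s <= 0) 0.5 else 0.5 * stats::pchisq(s, df = 1, lower.tail = FALSE)
  } else {
    stats::pchisq(s, df = df, lower.tail = FALSE)
  }
  list(statistic = s, df = if (boundary) 1 else df, boundary = boundary,
       p = max(p, .Machine$double.xmin))
}

#' Heritability estimate and boundary LRT for a trait
#'
#' Applies the inverse normal transform to the trait, fits the polygenic model
#' (full) and the sporadic model (constrained, `sigma2_g = 0`), and tests the
#' variance component with the half-half boundary mixture.
#'
#' @inheritParams fit_polygenic
#' @return list with `h2`, `statistic`, `p`, `fit_full`, `fit_constrained`.
#' @export
heritability_test <- function(y, X = NULL, K) {
  yt <- inverse_normal_transform(y)
  full <- fit_polygenic(yt, X, K)
  con <- fit_sporadic(yt, X)
  res <- lrt(full, con, boundary = TRUE)
  list(h2 = full$h2, statistic = res$statistic, p = res$p,
       fit_full = full, fit_constrained = con)
}

#' Test whether the mean fold change differs from zero
#'
#' Full model estimates the trait mean `m` freely (with covariates);
#' the constrained model fixes `m = 0`. With `use_kinship = TRUE` both are
#' polygenic fits on 2 Phi (the kinship-corrected test); otherwise both are
#' sporadic fits (classical independent-errors test). The mean is an interior
#' parameter, so the LRT uses plain chi-square(1).
#'
#' @param fc per-individual fold change (the trait).
#' @param X optional covariates.
#' @param K `kinship_matrix`/`kinship_eigen`; required if `use_kinship`.
#' @param use_kinship logical, default TRUE.
#' @return list with `mean`, `statistic`, `p`.
#' @export
mean_fc_test <- function(fc, X = NULL, K = NULL, use_kinship = TRUE) {
  if (use_kinship) {
    if (is.null(K)) stop("argument error: kinship matrix required when use_kinship = TRUE")
    full <- fit_polygenic(fc, X, K, include_mean = TRUE)
    con  <- fit_polygenic(fc, X, K, include_mean = FALSE)
  } else {
    full <- fit_sporadic(fc, X, include_mean = TRUE)
    con  <- fit_sporadic(fc, X, include_mean = FALSE)
  }
  res <- lrt(full, con, boundary = FALSE)
  list(mean = full$mean, statistic = res$statistic, p = res$p)
}

#' Association of drug sensitivity with differential expression
#'
#' Appends the per-probe fold change as a covariate to the polygenic model of
#' the sensitivity of drug response (SDR) and tests its regression coefficient
#' by constraining it to zero (interior LRT, chi-square(1)).
#'
#' @param sdr per-individual SDR values (the response).
#' @param fc per-individual fold change for the probe (the tested covariate).
#' @param X optional additional covariates.
#' @param K `kinship_matrix`/`kinship_eigen`.
#' @return list with `coefficient`, `statistic`, `p`.
#' @export
fc_sdr_association <- function(sdr, fc, X = NULL, K) {
  if (diff(range(fc)) == 0)
    stop("collinearity error: fold-change covariate is constant")
  Xfull <- if (is.null(X)) cbind(fc = fc) else cbind(X, fc = fc)
  full <- fit_polygenic(sdr, Xfull, K)
  con  <- fit_polygenic(sdr, X, K)
  res <- lrt(full, con, boundary = FALSE)
  list(coefficient = unname(full$beta["fc"]), statistic = res$statistic,
       p = res$p)
}
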