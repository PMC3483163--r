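# Independent oracles used across the suite. These re-derive quantities by
# routes unrelated to the package implementation (simulation, dense linear
# algebra, closed forms).

# Small hand-built pedigrees ------------------------------------------------

trio_df <- function() {
  data.frame(family_id = "T",
             individual_id = c("F", "M", "C"),
             father_id = c(NA, NA, "F"),
             mother_id = c(NA, NA, "M"),
             sex = c(1, 2, 1))
}

# two grandparents, two married sibs, their children (first cousins)
cousin_df <- function(n_gc = 2) {
  stopifnot(n_gc >= 2)
  gp <- c("gf", "gm"); sibs <- c("s1", "s2"); sp <- c("w1", "w2")
  gc <- paste0("c", seq_len(n_gc))
  data.frame(
    family_id = "K",
    individual_id = c(gp, sibs, sp, gc),
    father_id = c(NA, NA, "gf", "gf", NA, NA,
                  rep(c("s1", "s2"), length.out = n_gc)),
    mother_id = c(NA, NA, "gm", "gm", NA, NA,
                  rep(c("w1", "w2"), length.out = n_gc)),
    sex = c(1, 2, 1, 1, 2, 2, rep(1, n_gc)))
}

# Gene-dropping Monte-Carlo estimate of the kinship coefficient -------------
# Founders get unique allele pairs; children inherit one random allele from
# each parent; Phi-hat = P(random allele of i IBD random allele of j).
gene_drop_phi <- function(ped, i, j, n_drops = 2e5) {
  df <- as.data.frame(ped)
  ord <- order(df$generation)
  fi <- match(df$father_id, df$individual_id)
  mi <- match(df$mother_id, df$individual_id)
  n <- nrow(df)
  a1 <- matrix(0L, n, n_drops)
  a2 <- matrix(0L, n, n_drops)
  next_allele <- 0L
  for (k in ord) {
    inherit <- function(p) {
      if (is.na(p)) {
        next_allele <<- next_allele + 1L
        rep(next_allele, n_drops)
      } else {
        ifelse(stats::runif(n_drops) < 0.5, a1[p, ], a2[p, ])
      }
    }
    a1[k, ] <- inherit(fi[k])
    a2[k, ] <- inherit(mi[k])
  }
  ii <- match(i, df$individual_id); jj <- match(j, df$individual_id)
  ibd <- ((a1[ii, ] == a1[jj, ]) + (a1[ii, ] == a2[jj, ]) +
          (a2[ii, ] == a1[jj, ]) + (a2[ii, ] == a2[jj, ])) / 4
  list(phi = mean(ibd), se = stats::sd(ibd) / sqrt(n_drops))
}

# Dense multivariate-normal profile log-likelihood --------------------------
# Independent of the package's eigen-rotation: direct solve + determinant of
# V(h2) = h2 * 2Phi + (1 - h2) I with beta and total variance profiled out.
dense_profile_ll <- function(y, M, rel, h2) {
  n <- length(y)
  V <- h2 * rel + (1 - h2) * diag(n)
  Vi <- solve(V)
  if (ncol(M) > 0) {
    beta <- solve(t(M) %*% Vi %*% M, t(M) %*% Vi %*% y)
    r <- y - M %*% beta
  } else r <- y
  s2 <- drop(t(r) %*% Vi %*% r) / n
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + n * log(s2) + ld + n)
}

# a small random pedigree + relatedness for oracle-equivalence checks
random_small_kinship <- function(n_max = 30) {
  n_fam <- sample(1:3, 1)
  dfs <- lapply(seq_len(n_fam), function(f) {
    n_kids <- sample(2:6, 1)
    fam <- paste0("R", f)
    id <- function(k) paste0(fam, "_", k)
    data.frame(family_id = fam,
               individual_id = id(seq_len(n_kids + 2)),
               father_id = c(NA, NA, rep(id(1), n_kids)),
               mother_id = c(NA, NA, rep(id(2), n_kids)),
               sex = c(1, 2, sample(1:2, n_kids, replace = TRUE)))
  })
  ped <- pedigree(do.call(rbind, dfs))
  K <- kinship_matrix(ped)
  if (length(K$ids) > n_max) K <- kinship_matrix(ped, K$ids[seq_len(n_max)])
  K
}
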