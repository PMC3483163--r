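# Benjamini-Hochberg FDR, k-means clustering of bivariate fold changes,
# confidence ellipses, Kruskal-Wallis, overlaps, proportion chi-square.

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (`q_(i) = min_{j >= i} p_(j) n / j`, capped at 1)
#' via [stats::p.adjust()], returned in the original order.
#'
#' @param p raw p-values in (0, 1].
#' @param alpha significance level for the `significant` flag (q < alpha).
#' @param probe_ids optional identifiers.
#' @return data.frame with `probe_id` (if given), `p`, `q`, `significant`.
#' @export
bh_qvalues <- function(p, alpha = 0.05, probe_ids = NULL) {
  if (any(p <= 0 | p > 1)) stop("argument error: p-values must be in (0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(p = p, q = q, significant = q < alpha)
  if (!is.null(probe_ids)) out <- cbind(probe_id = probe_ids, out)
  out
}

#' k-means clustering of probes in (iFC, oFC) space
#'
#' Lloyd iterative refinement on Euclidean distance, best of `restarts`
#' seeded initializations; deterministic given `seed`.
#'
#' @param points numeric matrix/data.frame with two columns (iFC, oFC), one
#'   row per probe.
#' @param k number of clusters (default 4).
#' @param seed RNG seed for the restarts.
#' @param restarts number of random initializations.
#' @return Object of class `cluster_report`: list with `assignment`,
#'   `centers` (k x 2), `sizes`, `wcss`, `k`.
#' @export
kmeans_fc <- function(points, k = 4, seed = 17, restarts = 100) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (k <= 0 || k > n) stop("argument error: k must be in [1, n]")
  set.seed(seed)
  km <- tryCatch(
    stats::kmeans(pts, centers = k, nstart = restarts,
                  algorithm = "Lloyd", iter.max = 200),
    error = function(e) NULL,
    warning = function(w) NULL)
  if (is.null(km)) {
    # Lloyd can abort on a transiently empty cluster; Hartigan-Wong updates
    # centers point-by-point and cannot empty one.
    set.seed(seed)
    km <- stats::kmeans(pts, centers = k, nstart = restarts, iter.max = 200)
  }
  structure(list(assignment = unname(km$cluster),
                 centers = unname(km$centers),
                 sizes = unname(km$size),
                 wcss = km$tot.withinss,
                 k = k),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("k-means report: k =", x$k, ", sizes", paste(x$sizes, collapse = "/"),
      ", WCSS", format(x$wcss, digits = 4), "\n")
  invisible(x)
}

#' Relabel clusters to match reference centers
#'
#' k-means labels are arbitrary; this maps each fitted cluster to the nearest
#' reference center (e.g. published cluster means), resolving the assignment
#' by exhaustive permutation search minimizing total center distance.
#'
#' @param report a `cluster_report`.
#' @param reference k x 2 matrix of reference centers in the desired order.
#' @return `cluster_report` with relabelled `assignment`, `centers`, `sizes`.
#' @export
match_clusters <- function(report, reference) {
  k <- report$k
  ref <- as.matrix(reference)
  if (nrow(ref) != k) stop("argument error: reference must have k rows")
  perms <- all_permutations(k)
  cost <- vapply(seq_len(nrow(perms)), function(i) {
    sum(rowSums((report$centers[perms[i, ], , drop = FALSE] - ref)^2))
  }, numeric(1))
  best <- perms[which.min(cost), ]          # best[r] = fitted label for ref r
  relabel <- order(best)                    # relabel[fitted] = reference label
  report$assignment <- relabel[report$assignment]
  report$centers <- report$centers[best, , drop = FALSE]
  report$sizes <- report$sizes[best]
  report
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Per-cluster fold-change and enrichment summaries
#'
#' @param report a `cluster_report` (see [kmeans_fc()]).
#' @param points the clustered (iFC, oFC) matrix.
#' @param q_i,q_o optional FDR-adjusted q-values per probe (imatinib,
#'   omacetaxine) used for enrichment scores (mean -log10 q).
#' @return data.frame with one row per cluster: size, percent, mean iFC/oFC,
#'   enrichment scores.
#' @export
cluster_summary <- function(report, points, q_i = NULL, q_o = NULL) {
  pts <- as.matrix(points)
  out <- lapply(seq_len(report$k), function(cl) {
    idx <- report$assignment == cl
    data.frame(cluster = cl, size = sum(idx),
               percent = 100 * mean(idx),
               mean_ifc = if (any(idx)) mean(pts[idx, 1]) else NA_real_,
               mean_ofc = if (any(idx)) mean(pts[idx, 2]) else NA_real_,
               enrichment_i = if (!is.null(q_i) && any(idx))
                 enrichment_score(q_i[idx]) else NA_real_,
               enrichment_o = if (!is.null(q_o) && any(idx))
                 enrichment_score(q_o[idx]) else NA_real_)
  })
  do.call(rbind, out)
}

#' Overlap of two significance sets
#'
#' @param sig_a,sig_b probe-id sets, subsets of `universe`.
#' @param universe common probe universe.
#' @return list with `count` (size of intersection) and `fraction` (of the
#'   universe).
#' @export
significant_overlap <- function(sig_a, sig_b, universe) {
  if (!all(sig_a %in% universe) || !all(sig_b %in% universe))
    stop("argument error: sets must be subsets of the universe")
  both <- intersect(sig_a, sig_b)
  list(count = length(both), fraction = length(both) / length(universe))
}

#' Bivariate confidence ellipse of a point cloud
#'
#' Ellipse of the sample mean and covariance, semi-axes
#' `sqrt(eigenvalue * qchisq(level, 2))`, rotated to the leading eigenvector.
#'
#' @param points n x 2 matrix, n >= 3, non-collinear.
#' @param level coverage probability (default 0.95).
#' @return Object of class `ellipse_spec`: list with `center`, `semi_axes`,
#'   `rotation` (radians), `level`, `cov`.
#' @export
confidence_ellipse <- function(points, level = 0.95) {
  pts <- as.matrix(points)
  if (nrow(pts) < 3) stop("argument error: need >= 3 points")
  if (level <= 0 || level >= 1) stop("argument error: level must be in (0, 1)")
  S <- stats::cov(pts)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) <= 1e-12 * max(e$values))
    stop("degenerate-geometry error: singular covariance (collinear points)")
  r2 <- stats::qchisq(level, df = 2)
  structure(list(center = colMeans(pts),
                 semi_axes = sqrt(e$values * r2),
                 rotation = atan2(e$vectors[2, 1], e$vectors[1, 1]),
                 level = level, cov = S),
            class = "ellipse_spec")
}

#' Points on the boundary of a confidence ellipse (for plotting)
#' @param spec an `ellipse_spec`.
#' @param n number of boundary points.
#' @return n x 2 matrix.
#' @export
ellipse_points <- function(spec, n = 100) {
  t <- seq(0, 2 * pi, length.out = n)
  circ <- cbind(spec$semi_axes[1] * cos(t), spec$semi_axes[2] * sin(t))
  R <- matrix(c(cos(spec$rotation), sin(spec$rotation),
                -sin(spec$rotation), cos(spec$rotation)), 2, 2)
  sweep(circ %*% t(R), 2, spec$center, "+")
}

#' Kruskal-Wallis rank test between groups
#'
#' Tie-corrected H with chi-square reference (df = k - 1). If every value is
#' tied the statistic is reported as 0 with a warning (the tie correction is
#' degenerate there).
#'
#' @param groups list of >= 2 numeric vectors, none empty.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("argument error: need >= 2 groups")
  if (any(lengths(groups) == 0)) stop("argument error: empty group")
  vals <- unlist(groups)
  if (diff(range(vals)) == 0) {
    warning("all values tied; H reported as 0")
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  ht <- stats::kruskal.test(groups)
  list(H = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' One-sample proportion chi-square test
#'
#' Goodness of fit of `k` hits in `n` trials against a reference proportion
#' `p0`: `chi2 = (k - n p0)^2 / (n p0) + (n - k - n(1-p0))^2 / (n(1-p0))`,
#' df = 1, two-sided. Used for cis-regulation enrichment against a genome-wide
#' reference fraction.
#'
#' @param k hit count.
#' @param n trial count.
#' @param p0 reference proportion in (0, 1).
#' @return list with `chi2`, `p`.
#' @export
proportion_chi2 <- function(k, n, p0) {
  if (p0 <= 0 || p0 >= 1) stop("argument error: p0 must be in (0, 1)")
  if (k < 0 || k > n) stop("argument error: k must be in [0, n]")
  if (n * p0 < 1) warning("small expected count (n p0 < 1); chi-square unreliable")
  e1 <- n * p0
  e0 <- n * (1 - p0)
  chi2 <- (k - e1)^2 / e1 + ((n - k) - e0)^2 / e0
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}
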