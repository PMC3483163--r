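#' Construct a validated pedigree
#'
#' A pedigree is a set of families, each a directed acyclic graph of
#' parent-offspring links. Founders are individuals with both parents missing.
#' Monozygotic (MZ) twins may be flagged through an `mz_group` label; members
#' of one group are treated as genetically identical in all kinship
#' computations.
#'
#' @param df data.frame with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex` (1/"M" = male, 2/"F" = female) and
#'   optionally `age` (years) and `mz_group`. Missing parents are `NA`, `""`
#'   or `"0"`.
#' @return An object of class `pedigree`: the normalized data.frame with a
#'   `generation` column (founders = 0, children below their parents).
#' @export
pedigree <- function(df) {
  req <- c("family_id", "individual_id", "father_id", "mother_id", "sex")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("pedigree format error: missing column(s) ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  norm_id <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "" | x == "0"] <- NA_character_
    x
  }
  df$family_id     <- as.character(df$family_id)
  df$individual_id <- as.character(df$individual_id)
  df$father_id     <- norm_id(df$father_id)
  df$mother_id     <- norm_id(df$mother_id)
  df$sex <- normalize_sex(df$sex)
  if (!"age" %in% names(df)) df$age <- NA_real_
  df$age <- as.numeric(df$age)
  if (!"mz_group" %in% names(df)) df$mz_group <- NA_character_
  df$mz_group <- norm_id(df$mz_group)

  if (anyDuplicated(df$individual_id)) {
    dup <- unique(df$individual_id[duplicated(df$individual_id)])
    stop("pedigree format error: duplicated individual_id: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  # parent references must resolve within the same family
  for (col in c("father_id", "mother_id")) {
    ref <- df[[col]]
    has <- !is.na(ref)
    idx <- match(ref[has], df$individual_id)
    bad <- is.na(idx) | df$family_id[idx] != df$family_id[has]
    if (any(bad))
      stop("pedigree format error: unresolved ", col, " reference: ",
           paste(utils::head(ref[has][bad], 5), collapse = ", "))
  }
  df$generation <- ped_generations(df)   # errors on ancestry cycles

  # MZ group members must share both parents
  grp <- split(seq_len(nrow(df)), df$mz_group)
  for (g in grp) {
    if (length(unique(df$father_id[g])) > 1 || length(unique(df$mother_id[g])) > 1)
      stop("pedigree structure error: mz_group members do not share both parents")
  }
  class(df) <- c("pedigree", "data.frame")
  df
}

normalize_sex <- function(sex) {
  s <- toupper(as.character(sex))
  out <- rep(NA_integer_, length(s))
  out[s %in% c("1", "M", "MALE")] <- 1L
  out[s %in% c("2", "F", "FEMALE")] <- 2L
  if (anyNA(out)) stop("pedigree format error: unrecognized sex code")
  out
}

# Assign generation numbers by iterative relaxation; a cycle leaves some
# individual unnumbered after n passes.
ped_generations <- function(df) {
  n <- nrow(df)
  gen <- ifelse(is.na(df$father_id) & is.na(df$mother_id), 0L, NA_integer_)
  fi <- match(df$father_id, df$individual_id)
  mi <- match(df$mother_id, df$individual_id)
  if (any(fi == seq_len(n), na.rm = TRUE) || any(mi == seq_len(n), na.rm = TRUE))
    stop("pedigree structure error: individual listed as its own parent")
  for (pass in seq_len(n)) {
    todo <- which(is.na(gen))
    if (length(todo) == 0) break
    for (i in todo) {
      pg <- c(if (!is.na(fi[i])) gen[fi[i]] else 0L,
              if (!is.na(mi[i])) gen[mi[i]] else 0L)
      if (!anyNA(pg)) gen[i] <- max(pg) + 1L
    }
  }
  if (anyNA(gen))
    stop("pedigree structure error: ancestry cycle detected (individuals: ",
         paste(utils::head(df$individual_id[is.na(gen)], 5), collapse = ", "), ")")
  gen
}

#' Read a pedigree file
#'
#' Tab-delimited LINKAGE/FAM-style dialect with a header row and columns
#' `family_id`, `individual_id`, `father_id`, `mother_id`, `sex`, and optional
#' `age`, `mz_group`; `"0"` or empty denotes a missing parent.
#'
#' @param path file path.
#' @return A [pedigree] object.
#' @export
load_pedigree <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  pedigree(df)
}

#' Write a pedigree file in the same dialect read by [load_pedigree()]
#' @param ped a [pedigree] object.
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  df <- as.data.frame(ped)[, c("family_id", "individual_id", "father_id",
                               "mother_id", "sex", "age", "mz_group")]
  for (col in c("father_id", "mother_id", "mz_group"))
    df[[col]][is.na(df[[col]])] <- "0"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Founder individuals of a pedigree
#' @param ped a [pedigree] object.
#' @return character vector of founder ids (both parents missing).
#' @export
founders <- function(ped) {
  ped$individual_id[is.na(ped$father_id) & is.na(ped$mother_id)]
}

# Kinship coefficients for every pair in the pedigree, as a dense matrix.
#
# Standard recursion processed founders-first: phi(i,i) = (1 + phi(f,m))/2,
# phi(i,j) = (phi(f,j) + phi(m,j))/2 with a missing parent contributing 0.
# MZ twins are collapsed onto one genotype node before the recursion, so a
# twin pair has phi equal to self-kinship and descendants inherit correctly.
kinship_all <- function(ped) {
  ids <- ped$individual_id
  # genotype node = first member of the mz group, else self
  geno <- ids
  if (any(!is.na(ped$mz_group))) {
    for (g in unique(stats::na.omit(ped$mz_group))) {
      members <- ids[!is.na(ped$mz_group) & ped$mz_group == g]
      geno[ids %in% members] <- members[1]
    }
  }
  gmap <- stats::setNames(geno, ids)
  keep <- !duplicated(geno)
  gids <- geno[keep]
  gf <- gmap[ped$father_id[keep]]; gf[is.na(ped$father_id[keep])] <- NA
  gm <- gmap[ped$mother_id[keep]]; gm[is.na(ped$mother_id[keep])] <- NA
  ord <- order(ped$generation[keep])
  ng <- length(gids)
  phi <- matrix(0, ng, ng, dimnames = list(gids, gids))
  fi <- match(gf, gids); mi <- match(gm, gids)
  done <- integer(0)
  for (i in ord) {
    pfm <- if (!is.na(fi[i]) && !is.na(mi[i])) phi[fi[i], mi[i]] else 0
    phi[i, i] <- 0.5 * (1 + pfm)
    if (length(done) > 0) {
      pf <- if (!is.na(fi[i])) phi[fi[i], done] else 0
      pm <- if (!is.na(mi[i])) phi[mi[i], done] else 0
      v <- 0.5 * (pf + pm)
      phi[i, done] <- v
      phi[done, i] <- v
    }
    done <- c(done, i)
  }
  # expand back to individuals (twins share their genotype node's rows)
  idx <- match(gmap[ids], gids)
  out <- phi[idx, idx, drop = FALSE]
  dimnames(out) <- list(ids, ids)
  out
}

#' Kinship coefficient between two pedigree members
#'
#' The kinship coefficient Phi(i, j) is the probability that one allele
#' sampled at random from i and one from j are identical by descent. Founders
#' are assumed unrelated and non-inbred, so Phi(i, i) = 1/2 for a founder.
#' Members of one MZ group are genetically identical: Phi between them equals
#' the self-kinship.
#'
#' @param ped a [pedigree] object.
#' @param i,j individual ids.
#' @return Kinship coefficient in `[0, 1]`.
#' @export
kinship_coefficient <- function(ped, i, j) {
  phi <- kinship_all(ped)
  for (id in c(i, j))
    if (!id %in% rownames(phi)) stop("lookup error: unknown individual id: ", id)
  phi[i, j]
}

#' Relatedness (2 Phi) matrix over a set of study individuals
#'
#' Builds the covariance kernel of the additive polygenic effect used by the
#' variance-component models. Ancestors absent from `ids` still contribute to
#' the computation through the recursion.
#'
#' @param ped a [pedigree] object.
#' @param ids ordered individual ids to retain (default: all members).
#' @return Object of class `kinship_matrix`: list with `ids`, `phi`
#'   (kinship coefficients) and `relatedness` (2 Phi).
#' @export
kinship_matrix <- function(ped, ids = ped$individual_id) {
  if (length(ids) == 0) stop("argument error: empty id set")
  phi_all <- kinship_all(ped)
  missing_ids <- setdiff(ids, rownames(phi_all))
  if (length(missing_ids) > 0)
    stop("lookup error: ids not in pedigree: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  phi <- phi_all[ids, ids, drop = FALSE]
  rel <- 2 * phi
  ev <- eigen(rel, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("kinship matrix not positive semi-definite (min eigenvalue ",
         format(min(ev)), "); pedigree recursion violated")
  structure(list(ids = ids, phi = phi, relatedness = rel),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("kinship_matrix:", length(x$ids), "individuals, mean off-diagonal 2Phi =",
      format(mean(x$relatedness[upper.tri(x$relatedness)]), digits = 3), "\n")
  invisible(x)
}

#' Classify a pairwise relationship from its kinship coefficient
#'
#' Labels follow the usual Phi bands: MZ pair 1/2, first degree 1/4, second
#' degree 1/8, third degree 1/16 (e.g. first cousins), unrelated 0. Values off
#' these bands (inbred configurations) are labelled `"other"`.
#'
#' @param ped a [pedigree] object.
#' @param i,j individual ids.
#' @param tol numeric tolerance for band matching.
#' @return One of `"self"`, `"mz"`, `"first-degree"`, `"second-degree"`,
#'   `"third-degree"`, `"unrelated"`, `"other"`.
#' @export
classify_relationship <- function(ped, i, j, tol = 1e-9) {
  phi <- kinship_coefficient(ped, i, j)
  if (identical(i, j)) return("self")
  if (phi >= 0.5 - tol) return("mz")
  bands <- c("first-degree" = 0.25, "second-degree" = 0.125,
             "third-degree" = 0.0625, "unrelated" = 0)
  hit <- which(abs(phi - bands) <= tol)
  if (length(hit) == 1) names(bands)[hit] else "other"
}
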