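#' Pairwise matrix container
#'
#' Square symmetric matrix over the individuals of a panel, in one of two
#' roles: `distance` (zero diagonal, non-negative entries, `Inf` allowed as a
#' sentinel for undefined log-distances) or `similarity` (unit diagonal,
#' entries in `[0, 1]` as required by the genetic-distance sampler).
#'
#' @param values square numeric matrix with matching dimnames.
#' @param role `"distance"` or `"similarity"`.
#' @param measure name of the measure that produced it.
#' @param n_eff optional matrix of per-pair effective marker counts
#'   (missing-data bookkeeping).
#' @return a `pair_matrix` object.
#' @export
pair_matrix <- function(values, role = c("distance", "similarity"),
                        measure = "unknown", n_eff = NULL) {
  role <- match.arg(role)
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values))
  if (is.null(rownames(values))) {
    rownames(values) <- colnames(values) <- paste0("ind", seq_len(nrow(values)))
  }
  fin <- values[is.finite(values)]
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-12) {
    stop("pair matrix is not symmetric")
  }
  if (role == "distance") {
    if (any(abs(diag(values)) > 1e-12)) stop("distance matrix needs zero diagonal")
    if (any(fin < -1e-12)) stop("negative distances")
  } else {
    if (any(abs(diag(values) - 1) > 1e-10)) stop("similarity matrix needs unit diagonal")
    if (any(fin < -1e-10) || any(fin > 1 + 1e-10)) {
      stop("similarity entries must lie in [0, 1]")
    }
    values <- pmin(pmax(values, 0), 1)
  }
  structure(list(values = values, role = role, measure = measure,
                 ids = rownames(values), n_eff = n_eff),
            class = "pair_matrix")
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("pair_matrix (%s, %s): %d individuals\n", x$measure, x$role,
              nrow(x$values)))
  invisible(x)
}

# Pairs of (sum over shared markers of f(x, y), shared-marker count) for
# panels with missing data; f vectorized over marker vectors.
pairwise_apply <- function(d, f) {
  n <- nrow(d)
  obs <- !is.na(d)
  val <- matrix(0, n, n, dimnames = list(rownames(d), rownames(d)))
  cnt <- matrix(0, n, n, dimnames = dimnames(val))
  for (i in seq_len(n)) {
    for (k in i:n) {
      sh <- obs[i, ] & obs[k, ]
      cnt[i, k] <- cnt[k, i] <- sum(sh)
      if (any(sh)) {
        v <- f(d[i, sh], d[k, sh])
        val[i, k] <- val[k, i] <- v
      }
    }
  }
  list(val = val, cnt = cnt)
}

#' Nei's genetic distance on dosage data
#'
#' Treats each individual's dosage at a biallelic marker as within-individual
#' allele proportions `(d/q, 1 - d/q)` and evaluates Nei's standard distance
#' as a single global ratio across markers:
#' `D_XY = -ln( sum_jx p_jx,X p_jx,Y / sqrt(sum p^2_X * sum p^2_Y) )`,
#' with sums over both alleles and all markers non-missing in both
#' individuals. Orthogonal profiles (zero numerator) yield an `Inf` sentinel.
#'
#' @param panel a [dosage_panel].
#' @return a [pair_matrix] with role `distance`.
#' @export
nei_distance <- function(panel) {
  validate_panel(panel)
  d <- panel$dosages
  q <- panel$ploidy
  if (!anyNA(d)) {
    P <- d / q
    num <- tcrossprod(P) + tcrossprod(1 - P)
    ss <- rowSums(P^2 + (1 - P)^2)
    ratio <- num / sqrt(outer(ss, ss))
    n_eff <- matrix(ncol(d), nrow(d), nrow(d))
  } else {
    P <- d / q
    num <- pairwise_apply(P, function(x, y) {
      sum(x * y + (1 - x) * (1 - y)) /
        sqrt(sum(x^2 + (1 - x)^2) * sum(y^2 + (1 - y)^2))
    })
    if (any(num$cnt == 0)) stop("pair with no shared non-missing markers")
    ratio <- num$val
    n_eff <- num$cnt
  }
  ratio <- pmin(ratio, 1) # guard log of 1 + eps roundoff
  D <- -log(ratio)
  D[D < 0] <- 0
  diag(D) <- 0
  D <- (D + t(D)) / 2
  pair_matrix(D, "distance", "nei", n_eff = n_eff)
}

#' Euclidean distance on raw dosages
#'
#' `D_XY = sqrt( sum_j (X_j - Y_j)^2 )` with no centering or scaling. With
#' missing data the squared distance over shared markers is rescaled by
#' `r_total / r_shared` before the square root, so distances stay on the
#' full-panel scale.
#'
#' @param panel a [dosage_panel].
#' @return a [pair_matrix] with role `distance`.
#' @export
euclidean_distance <- function(panel) {
  validate_panel(panel)
  d <- panel$dosages
  m <- ncol(d)
  if (!anyNA(d)) {
    D <- as.matrix(dist(d))
    n_eff <- matrix(m, nrow(d), nrow(d))
  } else {
    sq <- pairwise_apply(d, function(x, y) sum((x - y)^2))
    if (any(sq$cnt == 0)) stop("pair with no shared non-missing markers")
    D <- sqrt(sq$val * m / sq$cnt)
    n_eff <- sq$cnt
  }
  diag(D) <- 0
  D <- (D + t(D)) / 2
  pair_matrix(D, "distance", "euclidean", n_eff = n_eff)
}

#' Jaccard similarity on dosage data
#'
#' Intersection-over-union of alternate-allele counts, as a ratio of sums
#' over markers: `S_XY = sum_j min(X_j, Y_j) / sum_j max(X_j, Y_j)` over
#' shared non-missing markers. A pair of identical reference homozygotes
#' (zero denominator) is defined to have similarity 1.
#'
#' @param panel a [dosage_panel].
#' @return a [pair_matrix] with role `similarity`.
#' @export
jaccard_similarity <- function(panel) {
  validate_panel(panel)
  d <- panel$dosages
  if (!anyNA(d)) {
    man <- as.matrix(dist(d, method = "manhattan"))
    s <- rowSums(d)
    tot <- outer(s, s, "+")
    smin <- (tot - man) / 2
    smax <- (tot + man) / 2
    n_eff <- matrix(ncol(d), nrow(d), nrow(d))
  } else {
    lo <- pairwise_apply(d, function(x, y) sum(pmin(x, y)))
    hi <- pairwise_apply(d, function(x, y) sum(pmax(x, y)))
    if (any(lo$cnt == 0)) stop("pair with no shared non-missing markers")
    smin <- lo$val
    smax <- hi$val
    n_eff <- lo$cnt
  }
  S <- ifelse(smax > 0, smin / smax, 1)
  diag(S) <- 1
  S <- (S + t(S)) / 2
  pair_matrix(S, "similarity", "jaccard", n_eff = n_eff)
}

#' Kosman-Leonard similarity for dosage data
#'
#' Ploidy-aware allele sharing: at marker j the two individuals share
#' `min(X_j, Y_j) + min(q - X_j, q - Y_j)` of their `q` allele copies, which
#' for dosages equals `q - |X_j - Y_j|`. The similarity is the average
#' shared fraction over shared non-missing markers, i.e.
#' `1 - Manhattan(X, Y) / (q * r)`.
#'
#' @param panel a [dosage_panel].
#' @return a [pair_matrix] with role `similarity`.
#' @export
kosman_leonard_similarity <- function(panel) {
  validate_panel(panel)
  d <- panel$dosages
  q <- panel$ploidy
  if (!anyNA(d)) {
    man <- as.matrix(dist(d, method = "manhattan"))
    S <- 1 - man / (q * ncol(d))
    n_eff <- matrix(ncol(d), nrow(d), nrow(d))
  } else {
    mn <- pairwise_apply(d, function(x, y) sum(abs(x - y)))
    if (any(mn$cnt == 0)) stop("pair with no shared non-missing markers")
    S <- 1 - mn$val / (q * mn$cnt)
    n_eff <- mn$cnt
  }
  diag(S) <- 1
  S <- (S + t(S)) / 2
  pair_matrix(S, "similarity", "kosman_leonard", n_eff = n_eff)
}

#' Convert a pairwise matrix to the similarity scale
#'
#' Measure-specific transforms used before genetic-distance sampling:
#' Euclidean distances map through `1 - D / max(D)`; Nei distances through
#' `1 - D`, clamped to `[0, 1]` (the `Inf` sentinel maps to 0). A matrix
#' already in the similarity role is returned unchanged.
#'
#' @param m a [pair_matrix].
#' @return a [pair_matrix] with role `similarity`.
#' @export
to_similarity <- function(m) {
  stopifnot(inherits(m, "pair_matrix"))
  if (m$role == "similarity") return(m)
  D <- m$values
  if (identical(m$measure, "nei")) {
    S <- 1 - D
    S[!is.finite(D)] <- 0
    S <- pmin(pmax(S, 0), 1)
  } else {
    mx <- max(D[is.finite(D)])
    if (mx == 0) {
      message("all-zero distance matrix; returning identity similarity")
      S <- matrix(1, nrow(D), ncol(D), dimnames = dimnames(D))
    } else {
      S <- 1 - D / mx
      S[!is.finite(D)] <- 0
    }
  }
  diag(S) <- 1
  pair_matrix(S, "similarity", paste0(m$measure, "_sim"), n_eff = m$n_eff)
}

#' Mantel correlation between two pairwise matrices
#'
#' Pearson correlation of the strictly-lower-triangle entries, with a
#' permutation p-value: rows/columns of the second matrix are permuted
#' jointly, and `p` is the proportion of permutations (the identity
#' included) with `|r_perm| >= |r_obs|`, so `p > 0` always. Similarity
#' inputs are converted to distances (`1 - S`) first so the two matrices are
#' compared in the same orientation.
#'
#' @param a,b [pair_matrix] objects over the same ids, in the same order.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return list with `r` (Mantel correlation) and `p` (permutation p-value).
#' @export
mantel_correlation <- function(a, b, n_perm = 999, seed = NULL) {
  stopifnot(inherits(a, "pair_matrix"), inherits(b, "pair_matrix"))
  if (!identical(a$ids, b$ids)) stop("pair matrices are over different ids")
  as_dist_mat <- function(m) {
    if (m$role == "similarity") 1 - m$values else m$values
  }
  A <- as_dist_mat(a)
  B <- as_dist_mat(b)
  if (any(!is.finite(A)) || any(!is.finite(B))) {
    stop("Mantel correlation undefined with non-finite entries")
  }
  lt <- lower.tri(A)
  x <- A[lt]
  y <- B[lt]
  if (sd(x) == 0 || sd(y) == 0) {
    stop("constant lower triangle: Mantel correlation undefined")
  }
  r_obs <- cor(x, y)
  local_seed(seed, {
    n <- nrow(A)
    hits <- 1L # identity permutation
    for (i in seq_len(n_perm)) {
      pp <- sample.int(n)
      r_p <- cor(x, B[pp, pp][lt])
      if (abs(r_p) >= abs(r_obs) - 1e-12) hits <- hits + 1L
    }
    list(r = r_obs, p = hits / (n_perm + 1))
  })
}
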