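# Distance-based analysis of molecular variance (Excoffier-style) on squared
# Euclidean dosage distances. Returns the variance components for a one-level
# grouping with the standard unequal-size coefficient n0.
amova_components <- function(d2, groups) {
  groups <- as.factor(groups)
  N <- nrow(d2)
  sizes <- table(groups)
  G <- nlevels(groups)
  if (G < 2) stop("need at least two strata")
  if (any(sizes < 2)) {
    stop("stratum of size 1: variance components undefined (",
         paste(names(sizes)[sizes < 2], collapse = ", "), ")")
  }
  ss_total <- sum(d2[lower.tri(d2)]) / N
  ss_within <- 0
  for (g in levels(groups)) {
    ix <- which(groups == g)
    dg <- d2[ix, ix, drop = FALSE]
    ss_within <- ss_within + sum(dg[lower.tri(dg)]) / length(ix)
  }
  ss_among <- ss_total - ss_within
  df_among <- G - 1
  df_within <- N - G
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (N - sum(sizes^2) / N) / (G - 1)
  sigma_within <- ms_within
  sigma_among <- (ms_among - ms_within) / n0
  list(sigma_among = sigma_among, sigma_within = sigma_within,
       ss_among = ss_among, ss_within = ss_within,
       df_among = df_among, df_within = df_within)
}

squared_euclid <- function(panel) {
  D <- euclidean_distance(panel)$values
  D^2
}

#' Among-group variance fraction by distance-based AMOVA
#'
#' Partitions the squared Euclidean dosage distances into among- and
#' within-stratum components (one-level AMOVA with the standard coefficient
#' for unequal group sizes) and returns
#' `sigma2_among / (sigma2_among + sigma2_within)`. A negative among-group
#' component estimate is truncated at 0.
#'
#' @param panel a [dosage_panel].
#' @param strata stratum labels; defaults to the labels stored in the panel.
#' @return the among-group fraction of molecular variance, in `[0, 1]`.
#' @export
amova_between_fraction <- function(panel, strata = panel$strata) {
  validate_panel(panel)
  if (is.null(strata)) stop("no stratum labels supplied")
  comp <- amova_components(squared_euclid(panel), strata)
  s_a <- max(comp$sigma_among, 0)
  s_a / (s_a + comp$sigma_within)
}

#' Pairwise differentiation between strata
#'
#' For each pair of strata runs a two-group analysis. The default
#' `"phi"` estimator is the distance-based Phi-statistic from the same AMOVA
#' machinery as [amova_between_fraction]; note that on dosage-coded data the
#' four allele copies of an individual shift jointly with the group mean, so
#' for dosages simulated as `Binomial(q, p_jk)` under a differentiation
#' parameter `F` the Phi-statistic estimates `q F / (1 + (q - 1) F)`, not
#' `F` itself. The `"hudson"` estimator is a frequency-based moment
#' estimator (Hudson's, as a multi-locus ratio of averages with finite-sample
#' correction), which estimates `F` directly.
#'
#' @param panel a [dosage_panel].
#' @param strata stratum labels; defaults to the panel's.
#' @param estimator `"phi"` (distance-based, default) or `"hudson"`
#'   (allele-frequency based).
#' @return symmetric matrix of pairwise estimates with zero diagonal.
#' @export
pairwise_fst <- function(panel, strata = panel$strata,
                         estimator = c("phi", "hudson")) {
  validate_panel(panel)
  estimator <- match.arg(estimator)
  if (is.null(strata)) stop("no stratum labels supplied")
  strata <- as.factor(strata)
  lv <- levels(strata)
  G <- length(lv)
  out <- matrix(0, G, G, dimnames = list(lv, lv))
  d2 <- if (estimator == "phi") squared_euclid(panel) else NULL
  for (i in seq_len(G - 1)) {
    for (k in (i + 1):G) {
      ix <- which(strata %in% c(lv[i], lv[k]))
      gg <- droplevels(strata[ix])
      est <- if (estimator == "phi") {
        comp <- amova_components(d2[ix, ix, drop = FALSE], gg)
        comp$sigma_among / (comp$sigma_among + comp$sigma_within)
      } else {
        hudson_fst(panel$dosages[ix, , drop = FALSE], gg, panel$ploidy)
      }
      out[i, k] <- out[k, i] <- est
    }
  }
  out
}

# Hudson's two-group Fst on allele counts (ratio of averages over loci,
# Bhatia et al. 2013 form). Each individual contributes `ploidy` allele
# copies; within an individual the copies are exchangeable draws from the
# stratum frequency, so copy-level counting is the right granularity here.
hudson_fst <- function(dos, groups, ploidy) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2)
  g <- as.integer(groups)
  num <- 0
  den <- 0
  for (j in seq_len(ncol(dos))) {
    x <- dos[, j]
    keep <- !is.na(x)
    xi <- x[keep]
    gi <- g[keep]
    n_i <- ploidy * tabulate(gi, 2)
    if (any(n_i < 2)) next
    p1 <- sum(xi[gi == 1]) / n_i[1]
    p2 <- sum(xi[gi == 2]) / n_i[2]
    num <- num + (p1 - p2)^2 -
      p1 * (1 - p1) / (n_i[1] - 1) - p2 * (1 - p2) / (n_i[2] - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  if (den == 0) return(0)
  num / den
}

#' Principal component scores of a dosage panel
#'
#' Centered (marker-mean imputed) dosage matrix decomposed by SVD; returns
#' per-individual scores and per-component explained-variance fractions.
#'
#' @param panel a [dosage_panel].
#' @param n_components number of components (truncated to the matrix rank,
#'   with a warning, when too large).
#' @return list with `scores` (individuals x components) and `pc_variance`
#'   (explained-variance fractions, non-increasing).
#' @export
pca_scores <- function(panel, n_components = 10) {
  validate_panel(panel)
  d <- panel$dosages
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d))
    d[idx] <- mu[(idx - 1) %/% nrow(d) + 1]
  }
  pc <- prcomp(d, center = TRUE, scale. = FALSE)
  total <- sum(pc$sdev^2)
  rank <- sum(pc$sdev^2 > 1e-12 * total)
  if (n_components > rank) {
    warning("n_components exceeds rank; truncated to ", rank)
    n_components <- rank
  }
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       pc_variance = (pc$sdev^2 / total)[seq_len(n_components)])
}

#' Population-structure summary report
#'
#' @param panel a [dosage_panel] with stratum labels.
#' @param n_components principal components to report.
#' @return list with `between_fraction`, `pairwise_fst` (Phi-based), and
#'   `pc_variance`.
#' @export
structure_report <- function(panel, n_components = 10) {
  list(between_fraction = amova_between_fraction(panel),
       pairwise_fst = pairwise_fst(panel),
       pc_variance = pca_scores(panel, n_components)$pc_variance)
}
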