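#' Simulation configuration for a synthetic tetraploid diversity panel
#'
#' Defaults emulate a SolCAP-like North American potato diversity panel:
#' 190 tetraploid individuals in 3 weakly differentiated subpopulations and
#' 3,262 biallelic dosage SNPs on 12 chromosomes. Differentiation follows the
#' Balding-Nichols model: each marker has an ancestral alternate-allele
#' frequency `p_j ~ Uniform(0.05, 0.95)` and stratum-specific frequencies
#' `p_jk ~ Beta` with mean `p_j` and variance `fst_target * p_j * (1 - p_j)`;
#' dosages are `Binomial(ploidy, p_jk)`. `fst_target = 0` collapses all
#' strata onto the ancestral frequencies.
#'
#' @param n_individuals panel size (default 190).
#' @param n_markers number of biallelic SNPs (default 3262).
#' @param ploidy default 4.
#' @param n_strata number of subpopulations (default 3).
#' @param stratum_proportions proportions summing to 1 (default
#'   `c(0.45, 0.35, 0.20)`).
#' @param fst_target Balding-Nichols differentiation parameter in `[0, 1)`
#'   (default 0.012, the weak-structure regime of a potato diversity panel
#'   with pairwise Fst of roughly 0.01-0.02 between market-class groups).
#' @param n_chrom chromosomes for the simulated map (default 12).
#' @param missing_rate fraction of dosage calls set missing at random
#'   (default 0).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_individuals = 190, n_markers = 3262, ploidy = 4,
                       n_strata = 3,
                       stratum_proportions = c(0.45, 0.35, 0.20),
                       fst_target = 0.012, n_chrom = 12, missing_rate = 0) {
  stopifnot(n_individuals >= 1, n_markers >= 1,
            fst_target >= 0, fst_target < 1,
            missing_rate >= 0, missing_rate < 1)
  if (n_strata > n_individuals) {
    stop("degenerate configuration: more strata than individuals")
  }
  if (length(stratum_proportions) != n_strata) {
    stratum_proportions <- rep(1 / n_strata, n_strata)
  }
  if (abs(sum(stratum_proportions) - 1) > 1e-8) {
    stop("stratum_proportions must sum to 1")
  }
  structure(list(n_individuals = n_individuals, n_markers = n_markers,
                 ploidy = ploidy, n_strata = n_strata,
                 stratum_proportions = stratum_proportions,
                 fst_target = fst_target, n_chrom = n_chrom,
                 missing_rate = missing_rate),
            class = "sim_config")
}

#' Simulate a synthetic autotetraploid dosage panel
#'
#' @param config a [sim_config].
#' @param seed RNG seed; a fixed seed reproduces the panel exactly.
#' @return a [dosage_panel] with stratum labels attached.
#' @export
simulate_panel <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(seed, {
    n <- config$n_individuals
    m <- config$n_markers
    q <- config$ploidy
    K <- config$n_strata
    sizes <- largest_remainder(n, config$stratum_proportions)
    strata <- rep(paste0("G", seq_len(K)), sizes)
    p_anc <- runif(m, 0.05, 0.95)
    F <- config$fst_target
    dos <- matrix(NA_real_, n, m)
    row0 <- 0
    for (k in seq_len(K)) {
      if (F > 0) {
        shape <- (1 - F) / F
        pk <- rbeta(m, shape1 = p_anc * shape, shape2 = (1 - p_anc) * shape)
      } else {
        pk <- p_anc
      }
      nk <- sizes[k]
      if (nk == 0) next
      dos[row0 + seq_len(nk), ] <-
        matrix(rbinom(nk * m, q, rep(pk, each = nk)), nk, m)
      row0 <- row0 + nk
    }
    if (config$missing_rate > 0) {
      drop <- runif(length(dos)) < config$missing_rate
      dos[drop] <- NA_real_
    }
    ids <- sprintf("ind%03d", seq_len(n))
    rownames(dos) <- ids
    chrom <- rep(seq_len(config$n_chrom), length.out = m)
    chrom <- sort(chrom)
    pos <- unlist(lapply(split(seq_len(m), chrom), function(ix) {
      sort(sample.int(1e8, length(ix)))
    }), use.names = FALSE)
    map <- data.frame(marker = sprintf("snp%05d", seq_len(m)),
                      chrom = as.character(chrom), pos = pos,
                      stringsAsFactors = FALSE)
    colnames(dos) <- map$marker
    dosage_panel(dos, ploidy = q, map = map,
                 strata = setNames(strata, ids))
  })
}

#' Simulate a quantitative trait on a dosage panel
#'
#' Genetic values are additive in allele dosage, `g_i = sum_j beta_j d_ij`
#' over `n_qtl` randomly placed QTL, with optional pairwise multiplicative
#' epistasis terms. Residuals are rescaled to the realized sample variance of
#' `g` so that the variance-ratio heritability `Var(g)/Var(y)` equals `h2`
#' exactly in every replicate (which makes parameter-recovery checks sharp).
#' `h2 = 1` returns the genetic values themselves.
#'
#' @param panel a [dosage_panel]; missing dosages enter QTL effects as the
#'   marker mean.
#' @param n_qtl number of QTL (`<= n_markers`).
#' @param h2 target broad-sense heritability in (0, 1].
#' @param effect_distribution `"gaussian"`, `"laplace"` (double exponential)
#'   or `"fixed"` (all effects +1).
#' @param epistasis optional data.frame/matrix with columns (qtl index a,
#'   qtl index b, effect) adding `effect * d_a * d_b` terms.
#' @param trait_name label stored with the trait.
#' @param seed RNG seed.
#' @return a `trait_set`: list with `values` (named phenotypes), `trait_name`,
#'   `h2`, and `truth` (genetic values, QTL indices and effects).
#' @export
simulate_trait <- function(panel, n_qtl, h2,
                           effect_distribution = c("gaussian", "laplace", "fixed"),
                           epistasis = NULL, trait_name = "trait",
                           seed = NULL) {
  validate_panel(panel)
  effect_distribution <- match.arg(effect_distribution)
  m <- ncol(panel$dosages)
  if (n_qtl > m) stop("n_qtl exceeds number of markers")
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  local_seed(seed, {
    d <- panel$dosages
    if (anyNA(d)) {
      mu <- colMeans(d, na.rm = TRUE)
      idx <- which(is.na(d))
      d[idx] <- mu[(idx - 1) %/% nrow(d) + 1]
    }
    qtl <- sort(sample.int(m, n_qtl))
    beta <- switch(effect_distribution,
                   gaussian = rnorm(n_qtl),
                   laplace = rexp(n_qtl) * sample(c(-1, 1), n_qtl, TRUE),
                   fixed = rep(1, n_qtl))
    g <- drop(d[, qtl, drop = FALSE] %*% beta)
    if (!is.null(epistasis)) {
      ep <- as.matrix(epistasis)
      for (r in seq_len(nrow(ep))) {
        g <- g + ep[r, 3] * d[, ep[r, 1]] * d[, ep[r, 2]]
      }
    }
    vg <- var(g)
    if (h2 < 1) {
      if (vg < .Machine$double.eps) {
        stop("genetic values are constant; cannot scale residuals to target h2")
      }
      e <- rnorm(length(g))
      # orthogonalize against g and fix the sample variance so the realized
      # variance-ratio heritability is exactly h2
      e <- e - mean(e)
      gc <- g - mean(g)
      e <- e - gc * sum(e * gc) / sum(gc^2)
      e <- e / sd(e) * sqrt(vg * (1 - h2) / h2)
      y <- g + e
    } else {
      y <- g
    }
    names(y) <- rownames(panel$dosages)
    structure(list(values = y, trait_name = trait_name, h2 = h2,
                   truth = list(genetic_values = setNames(g, names(y)),
                                qtl = qtl, effects = beta,
                                epistasis = epistasis, target_h2 = h2)),
              class = "trait_set")
  })
}

#' Realized variance-ratio heritability of a simulated trait
#'
#' @param trait a `trait_set` carrying simulation truth.
#' @return `Var(g) / Var(y)` computed from the stored genetic values.
#' @export
realized_h2 <- function(trait) {
  stopifnot(inherits(trait, "trait_set"), !is.null(trait$truth))
  var(trait$truth$genetic_values) / var(trait$values)
}
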