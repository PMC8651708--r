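new_sample_design <- function(training_ids, method, parameters = list(),
                              seed = NULL, diagnostics = list()) {
  stopifnot(!anyDuplicated(training_ids))
  structure(list(training_ids = training_ids, method = method,
                 parameters = parameters, seed = seed,
                 diagnostics = diagnostics),
            class = "sample_design")
}

#' @export
print.sample_design <- function(x, ...) {
  cat(sprintf("sample_design (%s): n = %d\n", x$method, length(x$training_ids)))
  invisible(x)
}

#' Simple random sample of a training set
#'
#' Uniform sampling without replacement: every candidate has the same
#' inclusion probability.
#'
#' @param candidates character vector of candidate ids.
#' @param n training-set size.
#' @param seed RNG seed.
#' @return a `sample_design`.
#' @export
srs_sample <- function(candidates, n, seed = NULL) {
  if (n > length(candidates)) stop("n exceeds the number of candidates")
  local_seed(seed, {
    new_sample_design(sample_ids(candidates, n), "SRS", seed = seed)
  })
}

#' Stratified proportional training sample
#'
#' Allocates `n_S = (n / N) * N_S` individuals to each stratum (rounded by
#' the largest-remainder rule so the allocation sums exactly to `n`) and
#' draws a simple random sample within each stratum.
#'
#' @param candidates candidate ids.
#' @param strata stratum labels, either named by candidate id or ordered as
#'   `candidates`.
#' @param n training-set size.
#' @param seed RNG seed.
#' @return a `sample_design` with the per-stratum allocation in
#'   `diagnostics$allocation`.
#' @export
stratified_sample <- function(candidates, strata, n, seed = NULL) {
  if (n > length(candidates)) stop("n exceeds the number of candidates")
  if (!is.null(names(strata))) strata <- strata[candidates]
  if (length(strata) != length(candidates) || anyNA(strata)) {
    stop("strata must label every candidate")
  }
  strata <- as.character(strata)
  lv <- unique(strata)
  sizes <- vapply(lv, function(g) sum(strata == g), integer(1))
  alloc <- largest_remainder(n, sizes)
  if (any(alloc > sizes)) {
    stop("allocation requires more individuals than a stratum contains")
  }
  local_seed(seed, {
    picked <- unlist(lapply(seq_along(lv), function(k) {
      sample_ids(candidates[strata == lv[k]], alloc[k])
    }), use.names = FALSE)
    new_sample_design(picked, "STRAT",
                      parameters = list(strata_levels = lv),
                      seed = seed,
                      diagnostics = list(allocation = setNames(alloc, lv)))
  })
}

# One run of the radial-exclusion process at radius r: pick a remaining
# candidate uniformly, discard every remaining candidate at distance < r
# from it, stop when n are picked or candidates are exhausted.
gd_process <- function(D, n, r) {
  remaining <- seq_len(nrow(D))
  picked <- integer(0)
  while (length(picked) < n && length(remaining) > 0) {
    k <- remaining[sample.int(length(remaining), 1)]
    picked <- c(picked, k)
    remaining <- remaining[D[remaining, k] >= r & remaining != k]
  }
  picked
}

#' Genetic-distance training sample (radial exclusion)
#'
#' Core-collection style sampler: individuals are drawn one at a time
#' uniformly at random, and after each draw all remaining candidates within
#' radial distance `r` of the draw (distance taken as `1 - similarity`) are
#' excluded from further sampling, so the sample spreads over the genetic
#' space. Sampling stops when `n` individuals are selected. The radius is
#' tied to the sample size: a larger `n` needs a smaller `r`. When `radius`
#' is not given it is tuned by bisection (each evaluation replaying the same
#' inner RNG substream) to the largest radius at which a sample of size `n`
#' is still attainable; a zero radius excludes nothing and reduces to simple
#' random sampling. Ties at exactly `r` survive the exclusion.
#'
#' @param similarity a [pair_matrix] with role `similarity` (unit diagonal,
#'   entries in `[0, 1]`).
#' @param candidates candidate ids (subset of the matrix ids).
#' @param n training-set size.
#' @param seed RNG seed.
#' @param radius optional fixed exclusion radius; errors if `n` cannot be
#'   reached at that radius.
#' @param bisect_iter bisection iterations for the radius search.
#' @return a `sample_design`; `diagnostics` records the final radius and the
#'   realized minimum pairwise distance of the sample.
#' @export
gd_sample <- function(similarity, candidates, n, seed = NULL, radius = NULL,
                      bisect_iter = 40) {
  stopifnot(inherits(similarity, "pair_matrix"),
            similarity$role == "similarity")
  if (!all(candidates %in% similarity$ids)) {
    stop("candidates missing from the similarity matrix")
  }
  if (n > length(candidates)) stop("n exceeds the number of candidates")
  D <- 1 - similarity$values[candidates, candidates, drop = FALSE]
  inner <- if (is.null(seed)) NULL else child_seed(seed, 1L)
  run <- function(r) local_seed(inner, gd_process(D, n, r))
  local_seed(seed, {
    if (is.null(inner)) {
      # unseeded: freeze an inner substream anyway so bisection evaluations
      # are comparable within this call
      inner <- sample.int(.Machine$integer.max, 1)
    }
    if (!is.null(radius)) {
      picked <- run(radius)
      if (length(picked) < n) {
        stop(sprintf("only %d of %d individuals attainable at radius %.4g",
                     length(picked), n, radius))
      }
      r_final <- radius
    } else {
      hi <- max(D) + 1e-9
      if (length(run(hi)) >= n) {
        r_final <- hi
        picked <- run(hi)
      } else {
        lo <- 0
        for (it in seq_len(bisect_iter)) {
          mid <- (lo + hi) / 2
          if (length(run(mid)) >= n) lo <- mid else hi <- mid
        }
        r_final <- lo
        picked <- run(lo)
      }
    }
    ids <- candidates[picked]
    sub <- D[picked, picked, drop = FALSE]
    min_d <- if (n > 1) min(sub[lower.tri(sub)]) else NA_real_
    new_sample_design(ids, "GD",
                      parameters = list(radius = r_final),
                      seed = seed,
                      diagnostics = list(r_final = r_final,
                                         min_pairwise_distance = min_d))
  })
}

# -- CDmean -----------------------------------------------------------------

as_A_matrix <- function(A) {
  if (inherits(A, "relationship_matrix")) A$A else as.matrix(A)
}

#' Generalized coefficient of determination of prediction contrasts
#'
#' Evaluates, for each target individual t, the CD of the contrast between t
#' and the candidate average, `c_t = e_t - (1/N_cand) 1_cand`, under the
#' mixed model with relationship matrix `A` and variance ratio
#' `lambda = sigma2_e / sigma2_g`:
#' `CD(c) = c' (A - lambda (Z'MZ + lambda A^-1)^-1) c / (c' A c)`,
#' where `Z` maps the phenotyped (training) individuals onto the panel and
#' `M` is the projector orthogonal to the intercept over the training
#' observations (`M = I - J / n_train`). An empty training set gives CD = 0
#' for every contrast.
#'
#' @param A a `relationship_matrix` (or plain symmetric matrix with ids).
#' @param training_ids ids of the phenotyped individuals.
#' @param target_ids ids whose contrasts are evaluated.
#' @param lambda residual-to-genetic variance ratio (`(1 - h2) / h2`).
#' @param candidate_ids ids defining the candidate average in the contrast;
#'   defaults to all individuals in `A`.
#' @param ridge small diagonal ridge added to `A` before inversion
#'   (default 1e-6).
#' @return named vector of CD values in `[0, 1)`, one per target.
#' @export
cd_contrast_values <- function(A, training_ids, target_ids, lambda,
                               candidate_ids = NULL, ridge = 1e-6) {
  Am <- as_A_matrix(A)
  ids <- rownames(Am)
  candidate_ids <- candidate_ids %||% ids
  stopifnot(all(training_ids %in% ids), all(target_ids %in% ids),
            all(candidate_ids %in% ids), lambda > 0)
  N <- nrow(Am)
  Ar <- Am + diag(ridge, N)
  t_vec <- as.numeric(ids %in% training_ids)
  n_t <- sum(t_vec)
  Ainv <- solve(Ar)
  ZMZ <- if (n_t > 0) diag(t_vec) - tcrossprod(t_vec) / n_t else
    matrix(0, N, N)
  B <- Ar - lambda * solve(ZMZ + lambda * Ainv)
  cmat <- -matrix(as.numeric(ids %in% candidate_ids), N,
                  length(target_ids)) / length(candidate_ids)
  ti <- match(target_ids, ids)
  cmat[cbind(ti, seq_along(ti))] <- cmat[cbind(ti, seq_along(ti))] + 1
  num <- colSums(cmat * (B %*% cmat))
  den <- colSums(cmat * (Ar %*% cmat))
  setNames(num / den, target_ids)
}

#' CDmean training-set selection by stochastic exchange search
#'
#' Maximizes the mean CD of prediction contrasts ([cd_contrast_values]) over
#' training sets of size `n`. Starting from a simple random sample, one
#' selected individual and one non-selected candidate are proposed for a
#' swap uniformly at random; the swap is accepted iff the mean CD strictly
#' increases, and the search stops after `max_stall` consecutive rejections.
#' The objective trajectory is therefore non-decreasing. With `target_ids`
#' given (training-test designs) the contrasts are those of the fixed
#' targets; otherwise (training-validation designs) the targets are the
#' currently non-selected candidates, recomputed after every accepted swap.
#'
#' @param A a `relationship_matrix` (or matrix with ids) covering candidates
#'   and targets.
#' @param candidates candidate ids for selection.
#' @param n training-set size; `n >= length(candidates)` trivially returns
#'   all candidates.
#' @param h2 heritability used to set `lambda = (1 - h2) / h2` (default 0.5,
#'   i.e. `lambda = 1`; a trait-agnostic intermediate value).
#' @param target_ids optional fixed prediction targets.
#' @param seed RNG seed.
#' @param max_stall stop after this many consecutive rejected proposals
#'   (default 2000).
#' @param n_starts independent restarts; the best objective wins (default 3).
#' @param ridge diagonal ridge for the `A` inverse (default 1e-6).
#' @return a `sample_design`; `diagnostics` holds the achieved mean CD and
#'   the mean CD of the initial random sample.
#' @export
cdmean_select <- function(A, candidates, n, h2 = 0.5, target_ids = NULL,
                          seed = NULL, max_stall = 2000, n_starts = 3,
                          ridge = 1e-6) {
  if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1) so that lambda > 0")
  lambda <- (1 - h2) / h2
  Am <- as_A_matrix(A)
  ids <- rownames(Am)
  stopifnot(all(candidates %in% ids))
  if (!is.null(target_ids)) stopifnot(all(target_ids %in% ids))
  if (n >= length(candidates)) {
    return(new_sample_design(candidates, "CDMEAN",
                             parameters = list(lambda = lambda, h2 = h2),
                             seed = seed,
                             diagnostics = list(note = "n >= candidates")))
  }
  keep <- union(candidates, target_ids)
  Am <- Am[keep, keep, drop = FALSE]
  ids <- rownames(Am)
  N <- nrow(Am)
  Ar <- Am + diag(ridge, N)
  Ainv <- solve(Ar)
  cand_idx <- match(candidates, ids)
  fixed_targets <- if (!is.null(target_ids)) match(target_ids, ids) else
    integer(0)
  mbar <- numeric(N)
  mbar[cand_idx] <- 1 / length(cand_idx)
  lamAinv <- lambda * Ainv

  one_start <- function(start_seed) {
    local_seed(start_seed, {
      sel0 <- cand_idx[sample.int(length(cand_idx), n)]
      # the compiled search draws its swap proposals from the same R RNG
      # stream, so the whole start is reproducible from start_seed
      res <- cdmean_search_cpp(Ar, lamAinv, sel0 - 1L, cand_idx - 1L,
                               fixed_targets - 1L,
                               targeted = length(fixed_targets) > 0,
                               mbar = mbar, lambda = lambda,
                               max_stall = as.integer(max_stall),
                               refresh_every = 200L)
      list(sel_idx = drop(res$sel) + 1L, obj = res$obj, obj0 = res$obj0,
           accepts = res$accepts)
    })
  }

  starts <- lapply(seq_len(n_starts), function(k) {
    one_start(if (is.null(seed)) NULL else child_seed(seed, k))
  })
  best <- starts[[which.max(vapply(starts, `[[`, numeric(1), "obj"))]]
  new_sample_design(ids[best$sel_idx], "CDMEAN",
                    parameters = list(lambda = lambda, h2 = h2,
                                      ridge = ridge, max_stall = max_stall,
                                      n_starts = n_starts,
                                      targeted = !is.null(target_ids)),
                    seed = seed,
                    diagnostics = list(cd_mean = best$obj,
                                       cd_mean_initial = best$obj0,
                                       accepted_swaps = best$accepts))
}
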