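# Single-kernel REML by spectral decomposition (EMMA-style profiled
# restricted likelihood), intercept-only fixed effects. `K` covers all
# individuals that need predictions; `y` is named by training ids.
# `lambda`, if given, fixes delta = sigma2_e / sigma2_g instead of REML.
kernel_reml_fit <- function(K, y, lambda = NULL) {
  ids <- rownames(K)
  train <- names(y)
  stopifnot(!is.null(train), all(train %in% ids))
  n <- length(y)
  if (n < 3) stop("need at least 3 training observations")
  if (var(y) < .Machine$double.eps) stop("zero phenotypic variance")
  Kt <- K[train, train, drop = FALSE]
  yc <- y - mean(y)
  P0y <- yc
  KP <- Kt - rowMeans(Kt)
  PKP <- KP - rep(colMeans(KP), each = n)
  PKP <- (PKP + t(PKP)) / 2
  eig <- eigen(PKP, symmetric = TRUE)
  if (min(eig$values) < -1e-6 * max(abs(eig$values), 1)) {
    stop("kernel is not positive semidefinite on the training set")
  }
  np <- n - 1
  xi <- pmax(eig$values[seq_len(np)], 0)
  eta <- drop(crossprod(eig$vectors[, seq_len(np), drop = FALSE], P0y))
  reml_ll <- function(log_delta) {
    delta <- exp(log_delta)
    S <- sum(eta^2 / (xi + delta))
    0.5 * (np * log(np / (2 * pi)) - np - np * log(S) -
             sum(log(xi + delta)))
  }
  if (is.null(lambda)) {
    grid <- seq(-12, 12, length.out = 41)
    vals <- vapply(grid, reml_ll, numeric(1))
    k <- which.max(vals)
    lo <- grid[max(1, k - 1)]
    hi <- grid[min(length(grid), k + 1)]
    opt <- optimize(reml_ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
    delta <- exp(opt$maximum)
    ll <- opt$objective
  } else {
    delta <- lambda
    ll <- reml_ll(log(delta))
  }
  sigma2_g <- sum(eta^2 / (xi + delta)) / np
  sigma2_e <- delta * sigma2_g
  V <- Kt + diag(delta + 1e-8, n)
  Vi_y <- solve(V, y)
  Vi_1 <- solve(V, rep(1, n))
  beta <- sum(Vi_y) / sum(Vi_1)
  alpha <- solve(V, y - beta)
  u_all <- drop(K[, train, drop = FALSE] %*% alpha)
  list(beta = beta, delta = delta, sigma2_g = sigma2_g, sigma2_e = sigma2_e,
       loglik = ll, predictions = setNames(beta + u_all, ids))
}

new_gp_fit <- function(model, fit, predict_ids, extra = list()) {
  structure(c(list(model = model, beta = fit$beta,
                   predictions = fit$predictions[predict_ids],
                   all_predictions = fit$predictions,
                   sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e,
                   lambda = fit$delta, loglik = fit$loglik), extra),
            class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("gp_fit (%s): %d predictions, intercept %.3f\n", x$model,
              length(x$predictions), x$beta))
  invisible(x)
}

#' GBLUP: genomic best linear unbiased prediction
#'
#' Fits `y = 1 beta + u + e` with `u ~ N(0, A sigma2_g)` and
#' `e ~ N(0, I sigma2_e)` on the training individuals, estimating the
#' variance ratio by REML through a spectral decomposition of the training
#' block of `A`, then predicts genotypic values of `predict_ids` as the
#' conditional mean under the joint normal with the full `A`.
#'
#' @param A a `relationship_matrix` (or symmetric matrix with ids) covering
#'   training and prediction individuals.
#' @param y named numeric vector of training phenotypes (BLUEs).
#' @param predict_ids individuals to predict (defaults to all ids in `A`).
#' @param lambda optional fixed variance ratio `sigma2_e / sigma2_g`
#'   (skips REML).
#' @return a `gp_fit` with `predictions`, variance components and REML
#'   log-likelihood.
#' @export
gblup_fit_predict <- function(A, y, predict_ids = NULL, lambda = NULL) {
  K <- as_A_matrix(A)
  predict_ids <- predict_ids %||% rownames(K)
  stopifnot(all(predict_ids %in% rownames(K)))
  fit <- kernel_reml_fit(K, y, lambda = lambda)
  new_gp_fit("GBLUP", fit, predict_ids)
}

#' RKHS regression with a Gaussian kernel of genetic distances
#'
#' Same mixed model as [gblup_fit_predict] with the relationship matrix
#' replaced by the kernel `K = exp(-D / theta)`, where `D` is the (by
#' default squared) Euclidean distance matrix on recoded dosages, normalized
#' by its own mean so the `(0, 1]` bandwidth grid is comparable across
#' panels. `theta` is chosen from `theta_grid` by maximum restricted
#' log-likelihood.
#'
#' @param panel a [dosage_panel].
#' @param y named numeric vector of training phenotypes.
#' @param predict_ids individuals to predict (default: all panel ids).
#' @param theta_grid candidate bandwidths in (0, 1]; default 20 evenly
#'   spaced values in (0.05, 1].
#' @param squared use squared Euclidean distances in the exponent
#'   (default TRUE).
#' @param normalize divide `D` by its mean off-diagonal entry (default TRUE).
#' @param lambda optional fixed variance ratio.
#' @return a `gp_fit`; `theta` holds the selected bandwidth and
#'   `grid_loglik` the profile over the grid.
#' @export
rkhs_fit_predict <- function(panel, y, predict_ids = NULL,
                             theta_grid = seq(0.05, 1, length.out = 20),
                             squared = TRUE, normalize = TRUE,
                             lambda = NULL) {
  validate_panel(panel)
  if (!length(theta_grid)) stop("empty theta grid")
  W <- recode_dosage(panel)
  ids <- rownames(W)
  predict_ids <- predict_ids %||% ids
  keep <- union(names(y), predict_ids)
  W <- W[keep, , drop = FALSE]
  D <- as.matrix(dist(W))
  if (squared) D <- D^2
  if (normalize) {
    md <- mean(D[lower.tri(D)])
    if (md > 0) D <- D / md
  }
  fits <- vector("list", length(theta_grid))
  lls <- rep(NA_real_, length(theta_grid))
  for (i in seq_along(theta_grid)) {
    Kth <- exp(-D / theta_grid[i])
    fits[[i]] <- tryCatch(kernel_reml_fit(Kth, y, lambda = lambda),
                          error = function(e) NULL)
    if (!is.null(fits[[i]])) lls[i] <- fits[[i]]$loglik
  }
  if (all(is.na(lls))) stop("all RKHS grid fits failed")
  best <- which.max(lls)
  new_gp_fit("RKHS", fits[[best]], predict_ids,
             extra = list(theta = theta_grid[best], grid_loglik = lls))
}

#' BayesC-pi whole-genome regression
#'
#' Fits `y = 1 beta + W b + e` by Gibbs sampling, where each marker effect
#' is zero with probability `pi` and `N(0, sigma2_b)` otherwise; `pi` gets a
#' uniform Beta(1, 1) prior and is estimated from the data (or fixed via
#' `pi_fixed`). Variance components have scaled-inverse-chi-squared priors
#' with `df_prior` degrees of freedom and scales set from the phenotypic
#' variance split at `R2` (BGLR-style defaults). Marker columns are centered
#' at their training means; predictions use posterior-mean effects.
#'
#' @param panel a [dosage_panel].
#' @param y named numeric vector of training phenotypes.
#' @param predict_ids individuals to predict (default: all panel ids).
#' @param n_iter total Gibbs iterations (default 5000).
#' @param burn_in discarded iterations (default 2500).
#' @param seed RNG seed; a fixed seed reproduces the chain exactly.
#' @param pi_fixed optionally fix the zero-effect proportion (0 = all
#'   markers in the model, a Bayesian ridge; 1 = intercept only).
#' @param df_prior prior degrees of freedom for both variances (default 5).
#' @param R2 prior variance split (default 0.5).
#' @param keep_chain keep post-burn-in samples of `sigma2_e` and `pi`
#'   (default FALSE).
#' @return a `gp_fit` with `pi` (posterior mean of the zero-effect
#'   proportion), `sigma2_b`, `sigma2_e`, posterior-mean effects in
#'   `effects`, and optionally `chain`.
#' @export
bayesc_fit_predict <- function(panel, y, predict_ids = NULL, n_iter = 5000,
                               burn_in = 2500, seed = NULL, pi_fixed = NULL,
                               df_prior = 5, R2 = 0.5, keep_chain = FALSE) {
  validate_panel(panel)
  stopifnot(burn_in < n_iter)
  if (var(y) < .Machine$double.eps) stop("zero phenotypic variance")
  W <- recode_dosage(panel)
  ids <- rownames(W)
  predict_ids <- predict_ids %||% ids
  train <- names(y)
  stopifnot(all(train %in% ids), all(predict_ids %in% ids))
  Wt <- W[train, , drop = FALSE]
  ctr <- colMeans(Wt)
  Wt <- sweep(Wt, 2, ctr)
  vy <- var(y)
  msx <- sum(apply(Wt, 2, var))
  if (msx <= 0) stop("no marker variance in the training set")
  S_e <- vy * (1 - R2) * (df_prior + 2)
  S_b <- vy * R2 * (df_prior + 2) / (0.5 * msx)
  estimate_pi <- is.null(pi_fixed)
  pi_init <- pi_fixed %||% 0.5
  res <- local_seed(seed, {
    bayesc_gibbs_cpp(Wt, as.numeric(y), as.integer(n_iter),
                     as.integer(burn_in), df_prior, S_b, df_prior, S_e,
                     pi_init, estimate_pi)
  })
  b <- drop(res$b_mean)
  preds_all <- setNames(res$mu_mean + drop(sweep(W, 2, ctr) %*% b), ids)
  fit <- list(beta = res$mu_mean, delta = NA_real_,
              sigma2_g = NA_real_, sigma2_e = res$s2e_mean,
              loglik = NA_real_, predictions = preds_all)
  extra <- list(pi = res$pi_mean, sigma2_b = res$s2b_mean,
                effects = b, n_iter = n_iter, burn_in = burn_in)
  if (keep_chain) {
    extra$chain <- list(sigma2_e = drop(res$s2e_chain),
                        pi = drop(res$pi_chain))
  }
  new_gp_fit("BAYESC", fit, predict_ids, extra = extra)
}

#' Prediction accuracy
#'
#' Pearson correlation between predicted genotypic values and observed
#' phenotypes over their common ids.
#'
#' @param predictions named numeric vector (or a `gp_fit`).
#' @param observed named numeric vector of phenotypes.
#' @return the correlation.
#' @export
accuracy <- function(predictions, observed) {
  if (inherits(predictions, "gp_fit")) predictions <- predictions$predictions
  shared <- intersect(names(predictions), names(observed))
  if (length(shared) < 3) stop("need at least 3 overlapping individuals")
  p <- predictions[shared]
  o <- observed[shared]
  if (sd(p) < .Machine$double.eps || sd(o) < .Machine$double.eps) {
    stop("accuracy undefined: zero variance in predictions or observations")
  }
  cor(p, o)
}
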