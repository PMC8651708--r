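# Independent brute-force oracles. These deliberately use naive double loops
# and dense algebra so they share no code path with the package internals.

rand_panel <- function(n, m, q = 4, missing_rate = 0, seed = 1,
                       strata = NULL) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  d <- matrix(rbinom(n * m, q, rep(p, each = n)), n, m)
  if (missing_rate > 0) {
    d[runif(n * m) < missing_rate] <- NA
    # keep every pair sharing at least one marker: force first marker observed
    d[, 1][is.na(d[, 1])] <- 0
  }
  rownames(d) <- sprintf("i%02d", seq_len(n))
  colnames(d) <- sprintf("m%03d", seq_len(m))
  map <- data.frame(marker = colnames(d),
                    chrom = as.character(rep(1:3, length.out = m)),
                    pos = seq_len(m))
  dosage_panel(d, ploidy = q, map = map, strata = strata)
}

shared_idx <- function(x, y) which(!is.na(x) & !is.na(y))

oracle_nei <- function(d, q) {
  n <- nrow(d)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    sh <- shared_idx(d[i, ], d[k, ])
    px <- cbind(d[i, sh] / q, 1 - d[i, sh] / q)
    py <- cbind(d[k, sh] / q, 1 - d[k, sh] / q)
    num <- sum(px * py)
    D[i, k] <- -log(num / sqrt(sum(px^2) * sum(py^2)))
  }
  D[D < 0 & D > -1e-12] <- 0
  D
}

oracle_euclid <- function(d) {
  n <- nrow(d)
  m <- ncol(d)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    sh <- shared_idx(d[i, ], d[k, ])
    D[i, k] <- sqrt(sum((d[i, sh] - d[k, sh])^2) * m / length(sh))
  }
  D
}

oracle_jaccard <- function(d) {
  n <- nrow(d)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    sh <- shared_idx(d[i, ], d[k, ])
    lo <- sum(pmin(d[i, sh], d[k, sh]))
    hi <- sum(pmax(d[i, sh], d[k, sh]))
    S[i, k] <- if (hi > 0) lo / hi else 1
  }
  S
}

oracle_kosman <- function(d, q) {
  n <- nrow(d)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    sh <- shared_idx(d[i, ], d[k, ])
    shared <- pmin(d[i, sh], d[k, sh]) + pmin(q - d[i, sh], q - d[k, sh])
    S[i, k] <- mean(shared / q)
  }
  S
}

oracle_vanraden <- function(d, q) {
  n <- nrow(d)
  m <- ncol(d)
  W <- (d - q / 2) / (q / 2)
  for (j in seq_len(m)) {
    W[is.na(W[, j]), j] <- mean(W[, j], na.rm = TRUE)
  }
  p <- colMeans(d, na.rm = TRUE) / q
  Q <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    Q[i, j] <- W[i, j] + 1 - 2 * p[j]
  }
  Q %*% t(Q) / (2 * sum(p * (1 - p)))
}

# Direct dense evaluation of the generalized CD of contrasts:
# CD(c) = diag[ c'(A - lambda (Z'MZ + lambda A^-1)^-1) c ] / diag[ c'Ac ]
oracle_cd <- function(A, train_idx, target_idx, lambda, cand_idx = NULL,
                      ridge = 1e-6) {
  N <- nrow(A)
  cand_idx <- if (is.null(cand_idx)) seq_len(N) else cand_idx
  A <- A + diag(ridge, N)
  n_t <- length(train_idx)
  Z <- matrix(0, n_t, N)
  for (r in seq_along(train_idx)) Z[r, train_idx[r]] <- 1
  X <- matrix(1, n_t, 1)
  M <- diag(n_t) - X %*% MASS::ginv(t(X) %*% X) %*% t(X)
  inner <- t(Z) %*% M %*% Z + lambda * solve(A)
  B <- A - lambda * solve(inner)
  vapply(target_idx, function(t) {
    cc <- rep(0, N)
    cc[cand_idx] <- -1 / length(cand_idx)
    cc[t] <- cc[t] + 1
    (t(cc) %*% B %*% cc) / (t(cc) %*% A %*% cc)
  }, numeric(1))
}

# Henderson mixed-model equations for GBLUP at a fixed variance ratio
# lambda = sigma2_e / sigma2_g; Z maps training observations to all
# individuals. Returns intercept + u for every individual in A.
oracle_mme_gblup <- function(A, y, train_idx, lambda, jitter = 1e-8) {
  N <- nrow(A)
  n <- length(train_idx)
  Z <- matrix(0, n, N)
  for (r in seq_len(n)) Z[r, train_idx[r]] <- 1
  X <- matrix(1, n, 1)
  Ainv <- solve(A + diag(jitter, N))
  lhs <- rbind(cbind(t(X) %*% X, t(X) %*% Z),
               cbind(t(Z) %*% X, t(Z) %*% Z + lambda * Ainv))
  rhs <- rbind(t(X) %*% y, t(Z) %*% y)
  sol <- solve(lhs, rhs)
  drop(sol[1] + sol[-1])
}

# Ridge regression with unpenalized intercept in marker space; predictions
# for all rows of Q.
oracle_ridge <- function(Q, y, train_idx, penalty) {
  Qt <- Q[train_idx, , drop = FALSE]
  n <- nrow(Qt)
  m <- ncol(Qt)
  lhs <- rbind(cbind(n, t(rep(1, n)) %*% Qt),
               cbind(t(Qt) %*% rep(1, n), t(Qt) %*% Qt + penalty * diag(m)))
  rhs <- c(sum(y), drop(t(Qt) %*% y))
  sol <- solve(lhs, rhs)
  drop(sol[1] + Q %*% sol[-1])
}

# Bayesian ridge (all markers in the model) Gibbs sampler in plain R, with
# the same scaled-inv-chi2 priors as the BayesC sampler; reference for the
# pi = 0 limit.
ref_bayes_ridge <- function(W, y, n_iter, burn_in, df_b, S_b, df_e, S_e) {
  n <- nrow(W)
  m <- ncol(W)
  wtw <- colSums(W^2)
  mu <- mean(y)
  b <- rep(0, m)
  s2b <- S_b / (df_b + 2)
  s2e <- S_e / (df_e + 2)
  e <- y - mu
  keep <- 0
  b_sum <- rep(0, m)
  mu_sum <- 0
  for (it in seq_len(n_iter)) {
    mu_new <- rnorm(1, mu + mean(e), sqrt(s2e / n))
    e <- e - (mu_new - mu)
    mu <- mu_new
    for (j in seq_len(m)) {
      z <- sum(W[, j] * e) + wtw[j] * b[j]
      C <- wtw[j] + s2e / s2b
      b_new <- rnorm(1, z / C, sqrt(s2e / C))
      e <- e + W[, j] * (b[j] - b_new)
      b[j] <- b_new
    }
    s2b <- (S_b + sum(b^2)) / rchisq(1, df_b + m)
    s2e <- (S_e + sum(e^2)) / rchisq(1, df_e + n)
    if (it > burn_in) {
      keep <- keep + 1
      b_sum <- b_sum + b
      mu_sum <- mu_sum + mu
    }
  }
  list(mu = mu_sum / keep, b = b_sum / keep)
}

# crude effective sample size from the autocorrelation function
ess <- function(x) {
  n <- length(x)
  ac <- acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  cutoff <- if (length(pos)) pos[1] - 1 else length(ac)
  denom <- 1 + 2 * sum(ac[seq_len(cutoff)])
  n / max(denom, 1e-8)
}
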