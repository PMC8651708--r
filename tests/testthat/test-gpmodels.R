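test_that("GBLUP at fixed lambda solves the mixed-model equations", {
  p <- rand_panel(8, 40, seed = 51)
  A <- vanraden_A(p)
  ids <- rownames(p$dosages)
  tr <- simulate_trait(p, n_qtl = 5, h2 = 0.8, seed = 1)
  train <- 1:5
  Ab <- A$A + diag(1e-6, 8) # same well-posed kernel on both routes
  for (lam in c(0.3, 1, 4)) {
    fit <- gblup_fit_predict(Ab, tr$values[train], ids, lambda = lam)
    ref <- oracle_mme_gblup(Ab, tr$values[train], train, lam, jitter = 0)
    expect_equal(unname(fit$all_predictions), ref, tolerance = 1e-8)
  }
})

test_that("GBLUP equals ridge regression on Q at the matched penalty", {
  p <- rand_panel(10, 50, seed = 52)
  q <- 4
  W <- recode_dosage(p)
  pj <- colMeans(p$dosages) / q
  Q <- sweep(W, 2, 2 * pj - 1, "-")
  cc <- 2 * sum(pj * (1 - pj))
  A <- Q %*% t(Q) / cc
  dimnames(A) <- list(rownames(W), rownames(W))
  y <- setNames(rnorm(6, 10), rownames(W)[1:6])
  lam <- 0.7
  fit <- gblup_fit_predict(A, y, rownames(W), lambda = lam)
  ref <- oracle_ridge(Q, unname(y), 1:6, penalty = lam * cc)
  expect_equal(unname(fit$all_predictions), unname(ref), tolerance = 1e-6)
})

test_that("infinite shrinkage collapses predictions to the training mean", {
  p <- rand_panel(12, 40, seed = 53)
  A <- vanraden_A(p)
  y <- setNames(rnorm(8, 5), rownames(p$dosages)[1:8])
  fit <- gblup_fit_predict(A, y, lambda = 1e10)
  expect_equal(unname(fit$predictions), rep(mean(y), 12), tolerance = 1e-4)
})

test_that("REML variance ratio is a local maximum of the profile", {
  p <- rand_panel(60, 200, seed = 54)
  A <- vanraden_A(p)
  tr <- simulate_trait(p, n_qtl = 20, h2 = 0.7, seed = 2)
  y <- tr$values[1:45]
  fit <- gblup_fit_predict(A, y)
  ll_at <- function(lam) gblup_fit_predict(A, y, lambda = lam)$loglik
  d <- fit$lambda
  expect_gte(fit$loglik + 1e-7, ll_at(d * 1.02))
  expect_gte(fit$loglik + 1e-7, ll_at(d * 0.98))
  expect_gte(fit$sigma2_g, 0)
  expect_gte(fit$sigma2_e, 0)
})

test_that("predictions shift by a constant when y does", {
  p <- rand_panel(15, 60, seed = 55)
  A <- vanraden_A(p)
  tr <- simulate_trait(p, n_qtl = 5, h2 = 0.8, seed = 3)
  y <- tr$values[1:10]
  g1 <- gblup_fit_predict(A, y)
  g2 <- gblup_fit_predict(A, y + 100)
  expect_equal(g2$all_predictions, g1$all_predictions + 100, tolerance = 1e-6)
  r1 <- rkhs_fit_predict(p, y, theta_grid = c(0.2, 0.6))
  r2 <- rkhs_fit_predict(p, y + 100, theta_grid = c(0.2, 0.6))
  expect_equal(r2$all_predictions, r1$all_predictions + 100, tolerance = 1e-6)
  b1 <- bayesc_fit_predict(p, y, n_iter = 600, burn_in = 300, seed = 9)
  b2 <- bayesc_fit_predict(p, y + 100, n_iter = 600, burn_in = 300, seed = 9)
  expect_equal(b2$all_predictions, b1$all_predictions + 100, tolerance = 1e-6)
})

test_that("RKHS kernel construction and bandwidth selection contracts hold", {
  p <- rand_panel(20, 80, seed = 56)
  tr <- simulate_trait(p, n_qtl = 8, h2 = 0.8, seed = 4)
  y <- tr$values[1:14]
  fit <- rkhs_fit_predict(p, y)
  # selected theta attains the grid maximum of the restricted likelihood
  expect_equal(fit$loglik, max(fit$grid_loglik, na.rm = TRUE))
  grid <- seq(0.05, 1, length.out = 20)
  expect_equal(fit$theta, grid[which.max(fit$grid_loglik)])
  # with the kernel frozen to A, the fit reduces exactly to GBLUP
  A <- vanraden_A(p)
  kf <- tetrasel:::kernel_reml_fit(A$A, y)
  gf <- gblup_fit_predict(A, y)
  expect_equal(kf$predictions, gf$all_predictions, tolerance = 1e-10)
  # K has unit diagonal for any theta
  W <- recode_dosage(p)
  D <- as.matrix(dist(W))^2
  D <- D / mean(D[lower.tri(D)])
  expect_equal(unname(diag(exp(-D / 0.3))), rep(1, 20))
})

test_that("BayesC with pi fixed at 1 reduces to the intercept model", {
  p <- rand_panel(15, 50, seed = 57)
  tr <- simulate_trait(p, n_qtl = 5, h2 = 0.9, seed = 5)
  y <- tr$values[1:12]
  fit <- bayesc_fit_predict(p, y, n_iter = 500, burn_in = 250, seed = 1,
                            pi_fixed = 1)
  expect_equal(unname(fit$effects), rep(0, 50))
  expect_equal(unname(fit$predictions), rep(fit$beta, 15))
  # and the intercept posterior centers on the training mean
  expect_equal(fit$beta, mean(y), tolerance = 0.25 * sd(y))
})

test_that("BayesC with pi fixed at 0 matches an independent ridge sampler", {
  p <- rand_panel(25, 30, seed = 58)
  tr <- simulate_trait(p, n_qtl = 30, h2 = 0.6, seed = 6)
  y <- tr$values
  W <- recode_dosage(p)
  Wc <- sweep(W, 2, colMeans(W))
  vy <- var(y)
  msx <- sum(apply(Wc, 2, var))
  S_e <- vy * 0.5 * 7
  S_b <- vy * 0.5 * 7 / (0.5 * msx)
  preds <- function(seed) {
    bayesc_fit_predict(p, y, n_iter = 3000, burn_in = 1000, seed = seed,
                       pi_fixed = 0)$all_predictions
  }
  ours_reps <- sapply(1:5, preds)
  ours <- rowMeans(ours_reps)
  set.seed(99)
  refs <- replicate(5, {
    r <- ref_bayes_ridge(Wc, unname(y), 3000, 1000, 5, S_b, 5, S_e)
    drop(r$mu + Wc %*% r$b)
  })
  ref_mean <- rowMeans(refs)
  mc_se <- sqrt(apply(refs, 1, var) / 5 + apply(ours_reps, 1, var) / 5)
  z <- abs(ours - ref_mean) / pmax(mc_se, 1e-3)
  expect_lt(mean(z), 3)            # agreement within Monte-Carlo error
  expect_lt(max(z), 6)             # no point-wise systematic discrepancy
  expect_gt(cor(ours, ref_mean), 0.999)
})

test_that("BayesC chains are reproducible and mix adequately", {
  p <- rand_panel(30, 60, seed = 59)
  tr <- simulate_trait(p, n_qtl = 6, h2 = 0.8, seed = 7)
  y <- tr$values[1:25]
  f1 <- bayesc_fit_predict(p, y, n_iter = 5000, burn_in = 2500, seed = 42,
                           keep_chain = TRUE)
  f2 <- bayesc_fit_predict(p, y, n_iter = 5000, burn_in = 2500, seed = 42,
                           keep_chain = TRUE)
  expect_identical(f1$chain$sigma2_e, f2$chain$sigma2_e)
  expect_identical(f1$effects, f2$effects)
  expect_gt(ess(f1$chain$sigma2_e), 50)
  expect_true(f1$pi >= 0 && f1$pi <= 1)
})

test_that("models rank as expected for sparse traits on held-out data", {
  # sparse architecture: marker-selecting and kernel models should not lose
  # to plain GBLUP on average (sign of the difference only)
  accs <- matrix(NA_real_, 20, 3,
                 dimnames = list(NULL, c("GBLUP", "BAYESC", "RKHS")))
  h2s <- rep(c(0.91, 0.85, 0.67), length.out = 20)
  for (s in 1:20) {
    p <- simulate_panel(sim_config(n_individuals = 160, n_markers = 600),
                        seed = 700 + s)
    tr <- simulate_trait(p, n_qtl = 10, h2 = h2s[s], seed = 800 + s)
    ids <- rownames(p$dosages)
    test <- ids[121:160]
    train <- ids[1:120]
    y <- tr$values[train]
    obs <- tr$values[test]
    A <- vanraden_A(p)
    accs[s, 1] <- accuracy(gblup_fit_predict(A, y, test), obs)
    accs[s, 2] <- accuracy(bayesc_fit_predict(p, y, test, n_iter = 800,
                                              burn_in = 400, seed = s), obs)
    accs[s, 3] <- accuracy(rkhs_fit_predict(p, y, test,
                                            theta_grid = seq(0.1, 1, 0.15)),
                           obs)
  }
  m <- colMeans(accs)
  expect_gte(m["BAYESC"], m["GBLUP"])
  expect_gte(m["RKHS"], m["GBLUP"] - 0.02)
})

test_that("accuracy is the Pearson correlation over shared ids", {
  x <- setNames(c(1, 2, 3, 4, 5), letters[1:5])
  expect_equal(accuracy(x, x), 1)
  expect_equal(accuracy(x, -x), -1)
  y <- setNames(c(2.3, 1.1, 4.8, 3.0, 5.5), letters[1:5])
  n <- 5
  textbook <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(accuracy(x, y), textbook, tolerance = 1e-12)
  expect_error(accuracy(x[1:2], y), "at least 3")
  expect_error(accuracy(setNames(rep(1, 5), letters[1:5]), y), "zero variance")
})
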