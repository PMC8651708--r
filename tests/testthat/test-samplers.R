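test_that("SRS is uniform, deterministic, and size-checked", {
  ids <- sprintf("g%02d", 1:10)
  expect_setequal(srs_sample(ids, 10, seed = 1)$training_ids, ids)
  expect_identical(srs_sample(ids, 4, seed = 7)$training_ids,
                   srs_sample(ids, 4, seed = 7)$training_ids)
  expect_error(srs_sample(ids, 11), "exceeds")
  # empirical inclusion frequencies of n = 1 draws are uniform
  draws <- vapply(1:10000, function(s) srs_sample(ids, 1, seed = s)$training_ids,
                  character(1))
  tab <- table(factor(draws, levels = ids))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("stratified allocation follows the largest-remainder rule", {
  # the printed allocation: N = 190, n = 100, strata 95/57/38 -> 50/30/20
  strata <- rep(c("A", "B", "C"), c(95, 57, 38))
  ids <- sprintf("g%03d", 1:190)
  names(strata) <- ids
  d <- stratified_sample(ids, strata, 100, seed = 2)
  expect_equal(unname(d$diagnostics$allocation), c(50L, 30L, 20L))
  got <- table(strata[d$training_ids])
  expect_equal(as.integer(got[c("A", "B", "C")]), c(50L, 30L, 20L))
  expect_equal(length(d$training_ids), 100L)

  # allocations always sum to n
  for (n in c(7, 23, 64)) {
    dn <- stratified_sample(ids, strata, n, seed = n)
    expect_equal(sum(dn$diagnostics$allocation), n)
    expect_equal(length(dn$training_ids), dn$parameters$n %||% n)
  }

  # one stratum degenerates to SRS under the same seed
  one <- rep("Z", 20)
  ids20 <- sprintf("h%02d", 1:20)
  names(one) <- ids20
  expect_setequal(stratified_sample(ids20, one, 8, seed = 5)$training_ids,
                  srs_sample(ids20, 8, seed = 5)$training_ids)
})

test_that("radial-exclusion sampling respects the exclusion radius", {
  # 4 points on a line at 0, 1, 2, 10 (distances scaled into [0, 1])
  pos <- c(p1 = 0, p2 = 1, p3 = 2, p4 = 10)
  D <- abs(outer(pos, pos, "-")) / 10
  S <- pair_matrix(1 - D, "similarity", "toy")
  ids <- names(pos)
  r <- 1.5 / 10
  feasible <- combn(ids, 3, simplify = FALSE)
  feasible <- Filter(function(s) {
    dd <- D[s, s]
    min(dd[lower.tri(dd)]) >= r
  }, feasible)
  # exhaustive enumeration of admissible triples: only {p1,p3,p4} etc.
  # at a fixed radius a sampling path may dead-end (e.g. picking the middle
  # point first); successful paths must return one of the enumerated
  # feasible triples, failing paths must error cleanly
  n_ok <- 0
  for (s in 1:40) {
    d <- tryCatch(gd_sample(S, ids, 3, seed = s, radius = r),
                  error = function(e) e)
    if (inherits(d, "error")) {
      expect_match(conditionMessage(d), "attainable")
    } else {
      n_ok <- n_ok + 1
      hit <- any(vapply(feasible, function(f) setequal(f, d$training_ids),
                        logical(1)))
      expect_true(hit)
      expect_gte(d$diagnostics$min_pairwise_distance, r)
    }
  }
  expect_gt(n_ok, 10)
  # radius too large for n = 3 on this geometry
  expect_error(gd_sample(S, ids, 3, seed = 1, radius = 0.5), "attainable")
  # r = 0 discards nothing: the full set is attainable even with an exact
  # duplicate present (distance 0 survives a strict "< r" exclusion)
  pos2 <- c(pos, p5 = 0)
  D2 <- abs(outer(pos2, pos2, "-")) / 10
  S2 <- pair_matrix(1 - D2, "similarity", "toy2")
  expect_equal(length(gd_sample(S2, names(pos2), 5, seed = 3,
                                radius = 0)$training_ids), 5)
})

test_that("tuned GD radius shrinks as the sample grows", {
  p <- rand_panel(60, 120, seed = 13)
  S <- to_similarity(euclidean_distance(p))
  ids <- rownames(p$dosages)
  r20 <- gd_sample(S, ids, 20, seed = 4)
  r45 <- gd_sample(S, ids, 45, seed = 4)
  expect_gt(r20$diagnostics$r_final, r45$diagnostics$r_final)
  for (d in list(r20, r45)) {
    expect_gte(d$diagnostics$min_pairwise_distance,
               d$diagnostics$r_final - 1e-12)
  }
  # determinism
  expect_identical(gd_sample(S, ids, 20, seed = 4)$training_ids,
                   r20$training_ids)
})

test_that("CD contrast values match the dense matrix oracle", {
  skip_if_not_installed("MASS")
  # 3 individuals, A = identity + ridge, lambda = 1, train {1,2}, target {3}
  A3 <- diag(3)
  dimnames(A3) <- list(c("a", "b", "c"), c("a", "b", "c"))
  got <- cd_contrast_values(A3, c("a", "b"), "c", lambda = 1)
  ref <- oracle_cd(A3, 1:2, 3, lambda = 1)
  expect_equal(unname(got), ref, tolerance = 1e-10)

  for (seed in 1:3) {
    p <- rand_panel(9, 40, seed = seed)
    A <- vanraden_A(p)
    ids <- rownames(p$dosages)
    train <- sample(9, 4)
    targets <- setdiff(1:9, train)[1:3]
    for (lam in c(0.5, 1, 3)) {
      got <- cd_contrast_values(A, ids[train], ids[targets], lambda = lam)
      ref <- oracle_cd(A$A, train, targets, lambda = lam)
      expect_equal(unname(got), ref, tolerance = 1e-10)
      expect_true(all(got >= 0 & got < 1))
    }
  }
})

test_that("CD of a contrast is zero without training data and grows with it", {
  p <- rand_panel(6, 30, seed = 77)
  A <- vanraden_A(p)
  ids <- rownames(p$dosages)
  expect_equal(unname(cd_contrast_values(A, character(0), ids, 1)),
               rep(0, 6), tolerance = 1e-9)
  # adding any individual to any training set never lowers any target CD
  subsets <- unlist(lapply(1:3, function(k) combn(ids, k, simplify = FALSE)),
                    recursive = FALSE)
  for (tr in subsets) {
    targets <- setdiff(ids, tr)
    base <- cd_contrast_values(A, tr, targets, 1)
    for (add in setdiff(ids, tr)) {
      bigger <- cd_contrast_values(A, c(tr, add), targets, 1)
      expect_true(all(bigger[targets] >= base[targets] - 1e-9))
    }
  }
})

test_that("exchange search attains the exhaustive CDmean optimum", {
  p <- rand_panel(8, 35, seed = 99)
  A <- vanraden_A(p)
  ids <- rownames(p$dosages)
  # enumerate all C(8,3) = 56 subsets with the dense objective (mean CD of
  # the non-selected candidates, TV-style)
  best <- -Inf
  for (tr in combn(ids, 3, simplify = FALSE)) {
    obj <- mean(cd_contrast_values(A, tr, setdiff(ids, tr), lambda = 1))
    if (obj > best) {
      best <- obj
      best_set <- tr
    }
  }
  d <- cdmean_select(A, ids, 3, h2 = 0.5, seed = 3, max_stall = 400,
                     n_starts = 2)
  expect_equal(d$diagnostics$cd_mean, best, tolerance = 1e-8)
  expect_setequal(d$training_ids, best_set)
})

test_that("CDmean search improves on random sampling and is monotone", {
  p <- rand_panel(40, 80, seed = 15)
  A <- vanraden_A(p)
  ids <- rownames(p$dosages)
  d <- cdmean_select(A, ids, 12, seed = 8, max_stall = 300, n_starts = 1)
  expect_gte(d$diagnostics$cd_mean, d$diagnostics$cd_mean_initial)
  # fast objective agrees with the dense evaluation of the final design
  dense <- mean(cd_contrast_values(A, d$training_ids,
                                   setdiff(ids, d$training_ids), lambda = 1))
  expect_equal(d$diagnostics$cd_mean, dense, tolerance = 1e-8)
  # beats the average of 100 random designs of the same size
  srs_obj <- vapply(1:100, function(s) {
    tr <- srs_sample(ids, 12, seed = 1000 + s)$training_ids
    mean(cd_contrast_values(A, tr, setdiff(ids, tr), lambda = 1))
  }, numeric(1))
  expect_gt(d$diagnostics$cd_mean, mean(srs_obj))
  # determinism and the h2 -> lambda mapping
  d2 <- cdmean_select(A, ids, 12, seed = 8, max_stall = 300, n_starts = 1)
  expect_identical(d$training_ids, d2$training_ids)
  expect_equal(d$parameters$lambda, 1) # h2 = 0.5
  expect_equal(cdmean_select(A, ids, 12, h2 = 0.2, seed = 1,
                             max_stall = 10)$parameters$lambda, 4)
})

test_that("targeted CDmean optimizes contrasts of the fixed target set", {
  p <- rand_panel(20, 60, seed = 16)
  A <- vanraden_A(p)
  ids <- rownames(p$dosages)
  targets <- ids[1:5]
  pool <- ids[6:20]
  d <- cdmean_select(A, pool, 6, target_ids = targets, seed = 2,
                     max_stall = 300, n_starts = 1)
  expect_true(all(d$training_ids %in% pool))
  dense <- mean(cd_contrast_values(A, d$training_ids, targets, lambda = 1,
                                   candidate_ids = pool))
  expect_equal(d$diagnostics$cd_mean, dense, tolerance = 1e-8)
  # trivial case: n >= |candidates|
  expect_setequal(cdmean_select(A, pool, 15, seed = 1)$training_ids, pool)
})

test_that("all samplers return exactly n unique candidate ids", {
  p <- rand_panel(30, 50, seed = 17, strata = rep(c("A", "B", "C"), 10))
  A <- vanraden_A(p)
  S <- to_similarity(euclidean_distance(p))
  ids <- rownames(p$dosages)
  designs <- list(
    srs_sample(ids, 11, seed = 1),
    stratified_sample(ids, p$strata, 11, seed = 1),
    gd_sample(S, ids, 11, seed = 1),
    cdmean_select(A, ids, 11, seed = 1, max_stall = 50, n_starts = 1))
  for (d in designs) {
    expect_equal(length(d$training_ids), 11L)
    expect_false(anyDuplicated(d$training_ids) > 0)
    expect_true(all(d$training_ids %in% ids))
  }
})
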