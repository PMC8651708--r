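single_locus_panel <- function(x, y) {
  d <- rbind(X = x, Y = y)
  colnames(d) <- paste0("m", seq_along(x))
  dosage_panel(d)
}

test_that("hand-evaluated single-pair examples are reproduced", {
  # Nei: AAAA (0 alt) vs AABB (2 alt) at one locus -> -ln(0.5 / sqrt(0.5))
  p <- single_locus_panel(0, 2)
  expect_equal(nei_distance(p)$values["X", "Y"], -log(0.5 / sqrt(0.5)),
               tolerance = 1e-12)
  # orthogonal homozygotes: infinite sentinel
  expect_equal(nei_distance(single_locus_panel(0, 4))$values["X", "Y"], Inf)
  # identity -> zero
  expect_equal(nei_distance(single_locus_panel(c(1, 3), c(1, 3)))$values["X", "Y"], 0)

  # Euclidean: (0,4,2) vs (4,0,2) -> sqrt(32)
  p2 <- dosage_panel(matrix(c(0, 4, 4, 0, 2, 2), 2,
                            dimnames = list(c("X", "Y"), c("a", "b", "c"))))
  expect_equal(euclidean_distance(p2)$values["X", "Y"], sqrt(32))

  # Jaccard: (2,0) vs (3,4) -> (2+0)/(3+4) = 2/7
  p3 <- single_locus_panel(c(2, 0), c(3, 4))
  expect_equal(jaccard_similarity(p3)$values["X", "Y"], 2 / 7)
  expect_equal(jaccard_similarity(single_locus_panel(c(2, 1), c(2, 1)))$values["X", "Y"], 1)
  expect_equal(jaccard_similarity(single_locus_panel(c(0, 0), c(4, 4)))$values["X", "Y"], 0)

  # Kosman-Leonard: X=2, Y=3 -> (min(2,3) + min(2,1)) / 4 = 0.75
  expect_equal(kosman_leonard_similarity(single_locus_panel(2, 3))$values["X", "Y"], 0.75)
  expect_equal(kosman_leonard_similarity(single_locus_panel(0, 4))$values["X", "Y"], 0)
  expect_equal(kosman_leonard_similarity(single_locus_panel(c(1, 2), c(1, 2)))$values["X", "Y"], 1)
})

test_that("all four measures match the brute-force oracle to 1e-10", {
  for (seed in 1:3) {
    for (mr in c(0, 0.15)) {
      p <- rand_panel(8, 30, missing_rate = mr, seed = seed)
      d <- p$dosages
      expect_equal(unname(nei_distance(p)$values), oracle_nei(d, 4),
                   tolerance = 1e-10)
      expect_equal(unname(euclidean_distance(p)$values), oracle_euclid(d),
                   tolerance = 1e-10)
      expect_equal(unname(jaccard_similarity(p)$values), oracle_jaccard(d),
                   tolerance = 1e-10)
      expect_equal(unname(kosman_leonard_similarity(p)$values),
                   oracle_kosman(d, 4), tolerance = 1e-10)
    }
  }
})

test_that("Kosman-Leonard equals 1 - Manhattan / (q r) on complete data", {
  p <- rand_panel(7, 25, seed = 5)
  man <- as.matrix(dist(p$dosages, method = "manhattan"))
  expect_equal(unname(kosman_leonard_similarity(p)$values),
               unname(1 - man / (4 * 25)), tolerance = 1e-12)
})

test_that("widening the dosage gap at one marker never raises similarity", {
  p <- rand_panel(2, 20, seed = 7)
  d <- p$dosages
  d[1, 5] <- 0
  for (y in 0:3) {
    d[2, 5] <- y
    lo <- dosage_panel(d)
    d2 <- d
    d2[2, 5] <- y + 1
    hi <- dosage_panel(d2)
    expect_lte(jaccard_similarity(hi)$values[1, 2],
               jaccard_similarity(lo)$values[1, 2] + 1e-12)
    expect_lte(kosman_leonard_similarity(hi)$values[1, 2],
               kosman_leonard_similarity(lo)$values[1, 2] + 1e-12)
  }
})

test_that("to_similarity applies the measure-specific transform", {
  p <- rand_panel(6, 20, seed = 2)
  e <- euclidean_distance(p)
  s <- to_similarity(e)
  expect_equal(s$role, "similarity")
  mx <- max(e$values)
  expect_equal(unname(s$values), unname(1 - e$values / mx), tolerance = 1e-12)
  # endpoints: the farthest pair maps to 0, self-pairs to 1
  expect_equal(min(s$values), 0)
  expect_equal(unname(diag(s$values)), rep(1, 6))

  # Nei: subtract from one with clamping; Inf sentinel -> 0
  nei_vals <- matrix(c(0, 0.25, 1.3, Inf,
                       0.25, 0, 0.1, 0.2,
                       1.3, 0.1, 0, 0.3,
                       Inf, 0.2, 0.3, 0), 4,
                     dimnames = list(letters[1:4], letters[1:4]))
  ns <- to_similarity(pair_matrix(nei_vals, "distance", "nei"))
  expect_equal(ns$values["a", "b"], 0.75)
  expect_equal(ns$values["a", "c"], 0)  # clamped from 1 - 1.3
  expect_equal(ns$values["a", "d"], 0)  # Inf sentinel
  # similarity input is returned unchanged
  j <- jaccard_similarity(p)
  expect_identical(to_similarity(j), j)
  # similarity invariants hold after every conversion
  for (m in list(s, ns)) {
    expect_true(all(m$values >= 0 & m$values <= 1))
    expect_equal(unname(diag(m$values)), rep(1, nrow(m$values)))
    expect_equal(m$values, t(m$values))
  }
})

test_that("Mantel correlation is exact for identical and affine inputs", {
  p <- rand_panel(10, 40, seed = 3)
  a <- euclidean_distance(p)
  expect_equal(mantel_correlation(a, a, n_perm = 19, seed = 1)$r, 1)
  b <- pair_matrix(2.5 * a$values, "distance", "scaled")
  expect_equal(mantel_correlation(a, b, n_perm = 19, seed = 1)$r, 1)
  cm <- matrix(1, 10, 10) - diag(10)
  dimnames(cm) <- dimnames(a$values)
  const <- pair_matrix(cm, "distance", "const")
  expect_error(mantel_correlation(a, const, n_perm = 19), "constant")
})

test_that("Mantel statistic agrees with vegan and p-value is calibrated", {
  skip_if_not_installed("vegan")
  p1 <- rand_panel(12, 30, seed = 8)
  p2 <- rand_panel(12, 30, seed = 9)
  a <- euclidean_distance(p1)
  b <- euclidean_distance(p2)
  ours <- mantel_correlation(a, b, n_perm = 199, seed = 42)
  ref <- vegan::mantel(as.dist(a$values), as.dist(b$values),
                       permutations = 199)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_gt(ours$p, 0)
  expect_lte(ours$p, 1)
  # unrelated panels: no signal, so p should not be extreme
  expect_gt(ours$p, 0.01)
})
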