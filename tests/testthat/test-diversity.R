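test_that("analytic Hill dissimilarity cases hold at q = 0, 1, 2", {
  p <- c(0.2, 0.3, 0.5)
  for (q in c(0, 1, 2)) {
    expect_equal(pairwise_dissimilarity(p, p, q)$d, 0, tolerance = 1e-12)
    expect_equal(pairwise_dissimilarity(c(1, 0), c(0, 1), q)$d, 1,
                 tolerance = 1e-12)
  }
  # the half-overlap pair: d = 0.5 at every order, with known decompositions
  p1 <- c(0.5, 0.5, 0)
  p2 <- c(0, 0.5, 0.5)
  h0 <- pairwise_dissimilarity(p1, p2, 0)
  expect_equal(h0$beta, 1.5, tolerance = 1e-12)
  expect_equal(h0$d, 0.5, tolerance = 1e-12)
  h1 <- pairwise_dissimilarity(p1, p2, 1)
  expect_equal(h1$beta, sqrt(2), tolerance = 1e-12)
  expect_equal(h1$d, 0.5, tolerance = 1e-12)
  h2 <- pairwise_dissimilarity(p1, p2, 2)
  expect_equal(h2$gamma, 8 / 3, tolerance = 1e-12)
  expect_equal(h2$alpha, 2, tolerance = 1e-12)
  expect_equal(h2$d, 0.5, tolerance = 1e-12)
  expect_error(pairwise_dissimilarity(p1, p2, -1), class = "invalid-input")
  expect_error(pairwise_dissimilarity(p1, c(0, 0, 0), 1),
               class = "invalid-input")
})

test_that("q = 1 equals the numerical limit and beta stays in [1, 2]", {
  set.seed(70)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    p1 <- rgamma(n, 1)
    p2 <- rgamma(n, 1)
    if (i %% 3 == 0) p2[sample(n, 1)] <- 0   # uneven support sometimes
    d1 <- pairwise_dissimilarity(p1, p2, 1)$d
    dlo <- pairwise_dissimilarity(p1, p2, 1 - 1e-6)$d
    dhi <- pairwise_dissimilarity(p1, p2, 1 + 1e-6)$d
    expect_lt(abs(dlo - d1), 1e-4)
    expect_lt(abs(dhi - d1), 1e-4)
    for (q in c(0, 0.5, 1, 2, 3)) {
      b <- pairwise_dissimilarity(p1, p2, q)$beta
      expect_gte(b, 1 - 1e-10)
      expect_lte(b, 2 + 1e-10)
    }
  }
})

test_that("d is invariant to taxa relabeling and zero-abundance padding", {
  set.seed(71)
  p1 <- rgamma(6, 1)
  p2 <- rgamma(6, 1)
  for (q in c(0, 1, 2)) {
    d <- pairwise_dissimilarity(p1, p2, q)$d
    perm <- sample(6)
    expect_equal(pairwise_dissimilarity(p1[perm], p2[perm], q)$d, d)
    expect_equal(pairwise_dissimilarity(c(p1, 0, 0), c(p2, 0, 0), q)$d, d)
  }
})

test_that("dissimilarity matrices are symmetric and match per-pair values", {
  set.seed(72)
  ab <- matrix(rgamma(40, 1), nrow = 8,
               dimnames = list(paste0("t", 1:8), paste0("s", 1:5)))
  D <- dissimilarity_matrix(ab, 1)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 5))
  vals <- combn(5, 2, function(ij) {
    pairwise_dissimilarity(ab[, ij[1]], ab[, ij[2]], 1)$d
  })
  expect_equal(median(D[upper.tri(D)]), median(vals))
  same <- cbind(a = ab[, 1], b = ab[, 1])
  expect_equal(unname(dissimilarity_matrix(same, 2)), matrix(0, 2, 2),
               ignore_attr = TRUE)
  ab0 <- ab
  ab0[, 3] <- 0
  expect_error(dissimilarity_matrix(ab0, 1), class = "empty-sample")
})

test_that("PCoA reproduces geometry and reports eigenvalues faithfully", {
  # three equidistant samples at d = 0.5
  D <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D) <- 0
  r <- pcoa(D)
  expect_equal(r$eigenvalues[1], r$eigenvalues[2], tolerance = 1e-10)
  emb <- as.matrix(dist(r$coordinates[, 1:2]))
  expect_equal(unname(emb), unname(D), tolerance = 1e-10)

  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  rz <- pcoa(z)
  expect_true(all(abs(rz$eigenvalues) < 1e-12))
  expect_equal(ncol(rz$coordinates), 0)

  # Euclidean-embeddable inputs reconstruct within 1e-8, and the eigenvalue
  # sum equals the trace of the Gower-centered matrix
  set.seed(73)
  X <- matrix(rnorm(7 * 3), 7, 3)
  DE <- as.matrix(dist(X))
  dimnames(DE) <- list(paste0("s", 1:7), paste0("s", 1:7))
  re <- pcoa(DE)
  expect_equal(unname(as.matrix(dist(re$coordinates))), unname(DE),
               tolerance = 1e-8)
  A <- -0.5 * DE^2
  J <- diag(7) - matrix(1 / 7, 7, 7)
  expect_equal(sum(re$eigenvalues), sum(diag(J %*% A %*% J)),
               tolerance = 1e-8)
  expect_error(pcoa(D[1:2, 1:2]), class = "invalid-input")
})

test_that("Mantel r is exact on identical and affine-related matrices", {
  set.seed(74)
  ab <- matrix(rgamma(60, 1), nrow = 10,
               dimnames = list(paste0("t", 1:10), paste0("s", 1:6)))
  dA <- dissimilarity_matrix(ab, 1)
  expect_equal(correlate_dissimilarities(dA, dA, n_perm = 99)$r, 1)
  dB <- 0.2 + 0.5 * dA
  diag(dB) <- 0
  expect_equal(correlate_dissimilarities(dA, dB, n_perm = 99)$r, 1,
               tolerance = 1e-12)
  expect_error(correlate_dissimilarities(dA[1:3, 1:3], dA[1:3, 1:3]),
               class = "insufficient-samples")
  # cross-check the statistic against an independent implementation
  dC <- dissimilarity_matrix(matrix(rgamma(60, 1), nrow = 10,
                                    dimnames = dimnames(ab)), 1)
  r <- correlate_dissimilarities(dA, dC, n_perm = 99)$r
  expect_equal(r, unname(vegan::mantel(dA, dC, permutations = 0)$statistic),
               tolerance = 1e-12)
})

test_that("Mantel inference is invariant to joint relabeling (exact)", {
  set.seed(75)
  n <- 5
  dA <- as.matrix(dist(matrix(rnorm(n * 2), n, 2)))
  dB <- as.matrix(dist(matrix(rnorm(n * 2), n, 2)))
  exact_p <- function(a, b) {
    ut <- upper.tri(a)
    r0 <- cor(a[ut], b[ut])
    rs <- vapply(all_perms(n), function(p) cor(a[ut], b[p, p][ut]),
                 numeric(1))
    mean(abs(rs) >= abs(r0) - 1e-12)
  }
  perm <- sample(n)
  expect_equal(exact_p(dA, dB), exact_p(dA[perm, perm], dB[perm, perm]),
               tolerance = 1e-12)
  # the sampled test is seeded and reproducible
  r1 <- correlate_dissimilarities(dA, dB, n_perm = 199, seed = 9)
  r2 <- correlate_dissimilarities(dA, dB, n_perm = 199, seed = 9)
  expect_identical(r1, r2)
})

test_that("prevalence grouping chunks sorted bins into groups of 36", {
  mk <- function(n) data.frame(bin_id = sprintf("b%03d", 1:n),
                               completeness = seq(50, 100, length.out = n),
                               has = rep(c(TRUE, FALSE), length.out = n))
  g72 <- prevalence_by_completeness(mk(72), "has")
  expect_equal(nrow(g72), 2)
  expect_true(all(g72$n == 36))
  expect_false(any(g72$partial))
  g40 <- prevalence_by_completeness(mk(40), "has")
  expect_equal(g40$n, c(36, 4))
  expect_equal(g40$partial, c(FALSE, TRUE))
  expect_true(all(diff(g40$completeness_min) > 0))
  allset <- transform(mk(20), has = TRUE)
  expect_equal(prevalence_by_completeness(allset, "has", 10)$fraction,
               c(1, 1))
})

test_that("shared_fraction reproduces the printed percentages", {
  expect_equal(shared_fraction(0.62), 38)
  expect_equal(shared_fraction(0.36), 64)
  expect_equal(shared_fraction(0.80), 20)
  expect_equal(shared_fraction(0), 100)
  expect_error(shared_fraction(1.2), class = "invalid-input")
})
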