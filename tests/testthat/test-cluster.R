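test_that("binary Pearson matches hand-computed values", {
  x <- c(1, 1, 0, 0, 1)
  expect_equal(binaryPearson(x, x), 1)
  expect_equal(binaryPearson(x, 1 - x), -1)
  expect_equal(binaryPearson(x, c(1, 0, 0, 0, 1)), 2 / 3)
  expect_error(binaryPearson(c(1, 1, 1), c(1, 0, 1)), "constant")
  expect_error(binaryPearson(c(1, 0), c(1, 0, 1)), "length")
})

test_that("proximity matrix equals the brute-force double-loop oracle", {
  set.seed(8)
  bits <- matrix(rbinom(30 * 8, 1, 0.4), nrow = 30,
                 dimnames = list(NULL, sprintf("s%d", 1:8)))
  ## ensure no constant columns
  bits[1, ] <- 1; bits[2, ] <- 0
  sim <- as.matrix(proximityMatrix(bits))
  oracle <- diag(8)
  for (i in 1:7) for (j in (i + 1):8)
    oracle[i, j] <- oracle[j, i] <- pearsonOracle(bits[, i], bits[, j])
  dimnames(oracle) <- dimnames(sim)
  expect_equal(sim, oracle, tolerance = 1e-12)
})

test_that("proximity matrix names constant spectra and permutes coherently", {
  bits <- cbind(a = c(1, 0, 1, 0), b = c(1, 1, 0, 0), c = c(1, 1, 1, 1))
  expect_error(proximityMatrix(bits), "c")
  bits <- cbind(a = c(1, 0, 1, 0), b = c(1, 1, 0, 0), c = c(0, 1, 1, 0))
  s1 <- as.matrix(proximityMatrix(bits))
  s2 <- as.matrix(proximityMatrix(bits[, c("c", "a", "b")]))
  expect_equal(s2[colnames(s1), colnames(s1)], s1)
  ## duplicated spectrum: off-diagonal exactly 1
  s3 <- as.matrix(proximityMatrix(cbind(bits, a2 = bits[, "a"])))
  expect_equal(s3["a", "a2"], 1)
})

test_that("UPGMA reproduces forced and hand-traced merges", {
  sim <- SimilarityMatrix(matrix(c(1, .8, .8, 1), 2, 2,
                                 dimnames = list(c("A", "B"), c("A", "B"))))
  tr <- upgmaTree(sim)
  expect_equal(tr@height, 0.1)

  D <- matrix(c(0, .2, .6, .2, 0, .8, .6, .8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- upgmaTree(D)
  expect_equal(tr3@height, c(0.1, 0.35))
  ## first merge joins A and B (leaves -1, -2)
  expect_equal(tr3@merge[1, ], c(-2L, -1L)[order(c(-2L, -1L))])
})

test_that("UPGMA agrees with the O(n^3) re-averaging oracle", {
  set.seed(99)
  for (rep in 1:50) {
    D <- as.matrix(dist(matrix(runif(12), 6)))
    dimnames(D) <- list(letters[1:6], letters[1:6])
    tr <- upgmaTree(D)
    expect_equal(copheneticFromTree(tr), upgmaCopheneticOracle(D),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("UPGMA heights match stats::hclust average linkage", {
  set.seed(4)
  D <- as.matrix(dist(matrix(rnorm(20), 10)))
  dimnames(D) <- list(paste0("l", 1:10), paste0("l", 1:10))
  tr <- upgmaTree(D)
  hc <- stats::hclust(as.dist(D), method = "average")
  expect_equal(2 * tr@height, hc$height, tolerance = 1e-12)
})

test_that("novelty verdicts follow the 0.5 threshold strictly", {
  set.seed(12)
  bits <- matrix(rbinom(40 * 5, 1, 0.5), 40,
                 dimnames = list(NULL, c("q", sprintf("ref%d", 1:4))))
  bits[1:2, ] <- c(1, 0)
  calls <- callNovelty(bits, "q", sprintf("ref%d", 1:4))
  sims <- vapply(sprintf("ref%d", 1:4), function(r)
    binaryPearson(bits[, "q"], bits[, r]), numeric(1))
  expect_equal(calls$best_similarity, max(sims))
  expect_identical(calls$verdict,
                   if (max(sims) < 0.5) "candidate_novel" else "assigned")

  ## query identical to a reference is assigned with similarity 1
  bits2 <- cbind(bits, refq = bits[, "q"])
  c2 <- callNovelty(bits2, "q", c(sprintf("ref%d", 1:4), "refq"))
  expect_equal(c2$best_similarity, 1)
  expect_identical(c2$verdict, "assigned")
  expect_identical(c2$best_match, "refq")

  ## threshold straddling: verdict flips around the best similarity
  eps <- 1e-6
  s <- max(sims)
  expect_identical(callNovelty(bits, "q", sprintf("ref%d", 1:4),
                               threshold = s + eps)$verdict, "candidate_novel")
  expect_identical(callNovelty(bits, "q", sprintf("ref%d", 1:4),
                               threshold = s - eps)$verdict, "assigned")
  expect_error(callNovelty(bits, "q", character(0)), "empty")
})

test_that("Mantel statistic and p-value behave as specified", {
  set.seed(2)
  A <- randomSymmetricMatrix(6)
  r <- mantelTest(A, A, nPermutations = 99, seed = 1)
  expect_equal(r@statistic, 1)
  expect_equal(r@pValue, 1 / 100)  # smallest achievable with 99 perms

  B <- randomSymmetricMatrix(6)
  r1 <- mantelTest(A, B, nPermutations = 999, seed = 42)
  r2 <- mantelTest(A, B, nPermutations = 999, seed = 42)
  expect_identical(r1@pValue, r2@pValue)  # seed-reproducible

  expect_error(mantelTest(A[1:3, 1:3], B[1:3, 1:3]), "at least 4")
  Bm <- B; rownames(Bm) <- colnames(Bm) <- paste0("x", 1:6)
  expect_error(mantelTest(A, Bm), "label mismatch")
  C <- A; C[upper.tri(C)] <- 0.5; C[lower.tri(C)] <- 0.5
  expect_error(mantelTest(A, C), "constant")
})

test_that("Mantel p matches exhaustive enumeration on 4x4 matrices", {
  set.seed(31)
  A <- randomSymmetricMatrix(4)
  B <- randomSymmetricMatrix(4)
  exact <- mantelExactOracle(A, B)
  est <- mantelTest(A, B, nPermutations = 9999, seed = 7)
  expect_equal(est@statistic, exact$r, tolerance = 1e-12)
  se <- sqrt(exact$p * (1 - exact$p) / 9999)
  expect_lt(abs(est@pValue - exact$p), 4 * se + 2e-4)
})

test_that("Mantel statistic agrees with vegan's implementation", {
  set.seed(17)
  A <- randomSymmetricMatrix(8)
  B <- randomSymmetricMatrix(8)
  mine <- mantelTest(A, B, nPermutations = 99, seed = 1)
  ref <- vegan::mantel(as.dist(A), as.dist(B), permutations = 99)
  expect_equal(mine@statistic, unname(ref$statistic), tolerance = 1e-12)
})
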