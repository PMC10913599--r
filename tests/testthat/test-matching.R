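test_that("exhaustive matching inverts a permuted copy and honors ties", {
  set.seed(51)
  C1 <- matrix(rnorm(15), 3, 5)
  shuffle <- c(3L, 1L, 2L)
  C2 <- C1[shuffle, ] * 2      # scaled copy: cosine similarity 1
  m <- match_exhaustive(C1, C2, "cosine")
  expect_equal(m$mean_similarity, 1)
  expect_identical(m$permutation, order(shuffle))
  expect_equal(centroid_dissimilarity(C1, C2, m), 0)

  # all-tied instance -> lexicographically smallest permutation
  v <- c(1, 2)
  tied <- match_exhaustive(rbind(v, v), rbind(v, v), "cosine")
  expect_identical(tied$permutation, 1:2)

  expect_error(match_exhaustive(matrix(rnorm(90), 9, 10),
                                matrix(rnorm(90), 9, 10)),
               "K = 9")
})

test_that("exhaustive matching equals an independent brute-force oracle", {
  set.seed(52)
  for (i in 1:60) {
    K <- sample(3:5, 1)
    C1 <- matrix(rnorm(K * 4), K, 4)
    C2 <- matrix(rnorm(K * 4), K, 4)
    for (mode in c("cosine", "euclidean")) {
      m <- match_exhaustive(C1, C2, mode)
      o <- oracle_best_matching(C1, C2, mode)
      expect_equal(m$mean_similarity, o$value, tolerance = 1e-12)
      expect_identical(m$permutation, as.integer(o$permutation))
    }
  }
})

test_that("greedy matching never beats exhaustive and follows its rule", {
  set.seed(53)
  for (i in 1:100) {
    K <- sample(2:6, 1)
    C1 <- matrix(rnorm(K * 3), K, 3)
    C2 <- matrix(rnorm(K * 3), K, 3)
    g <- match_greedy(C1, C2, "cosine")
    e <- match_exhaustive(C1, C2, "cosine")
    expect_lte(g$mean_similarity, e$mean_similarity + 1e-12)
    ge <- match_greedy(C1, C2, "euclidean")
    ee <- match_exhaustive(C1, C2, "euclidean")
    expect_gte(ge$mean_similarity, ee$mean_similarity - 1e-12)
  }

  # identical sets -> identity matching with similarity 1
  C <- diag(3)
  gi <- match_greedy(C, C, "cosine")
  expect_identical(gi$permutation, 1:3)
  expect_equal(gi$mean_similarity, 1)

  # adversarial instance where greedy is strictly suboptimal:
  # s33 = 1 is picked first, then (1,1); optimal swaps states 1 and 2
  C1a <- diag(3)
  C2a <- rbind(c(0.9, 0.436, 0), c(0.88, 0.40, 0.256), c(0, 0, 1))
  g2 <- match_greedy(C1a, C2a, "cosine")
  e2 <- match_exhaustive(C1a, C2a, "cosine")
  expect_identical(g2$permutation, c(1L, 2L, 3L))  # hand trace of greedy rule
  expect_identical(e2$permutation, c(2L, 1L, 3L))
  expect_lt(g2$mean_similarity, e2$mean_similarity)
})

test_that("centroid dissimilarity attains its 0 and 2 extremes", {
  set.seed(54)
  v <- rnorm(6); v <- v / sqrt(sum(v^2))
  A <- rbind(v, 2 * v)
  B <- rbind(-v, -3 * v)
  m <- match_exhaustive(A, B, "cosine")
  expect_equal(centroid_dissimilarity(A, B, m), 2)
  expect_equal(centroid_dissimilarity(A, A), 0)

  # K = 2 orthogonal-pair instance, hand cosines: best matching pairs the
  # parallel vectors, mean cos = 1; crossed matching would give 0
  C1 <- rbind(c(1, 0), c(0, 1))
  C2 <- rbind(c(0, 3), c(2, 0))
  m2 <- match_exhaustive(C1, C2, "cosine")
  expect_identical(m2$permutation, c(2L, 1L))
  expect_equal(centroid_dissimilarity(C1, C2, m2), 0)
  expect_error(centroid_dissimilarity(C1, rbind(c(0, 0), c(1, 0))),
               "zero-norm")
})

test_that("tv_distance and frobenius_distance are correct metrics", {
  expect_equal(tv_distance(c(0.5, 0.5), c(0.2, 0.8)), 0.3)
  expect_equal(tv_distance(c(1, 2), c(1, 2)), 0)
  expect_error(tv_distance(1:2, 1:3), "equal length")

  expect_equal(frobenius_distance(rbind(c(0, 1), c(1, 0)),
                                  rbind(c(0, 1), c(0, 0))), 1)
  expect_equal(frobenius_distance(diag(3), diag(3)), 0)

  set.seed(55)
  for (i in 1:20) {
    a <- runif(4); b <- runif(4); c <- runif(4)
    expect_equal(tv_distance(a, b), tv_distance(b, a))
    expect_lte(tv_distance(a, c), tv_distance(a, b) + tv_distance(b, c) + 1e-12)
    A <- matrix(rnorm(9), 3); B <- matrix(rnorm(9), 3)
    expect_equal(frobenius_distance(A, B), sqrt(sum((as.vector(A - B))^2)))
  }
})

test_that("session_discrepancy: relabeled copies give 0 and values are symmetric", {
  set.seed(56)
  K <- 3
  lab <- sample.int(K, 40, replace = TRUE)
  cen <- matrix(rnorm(K * 5), K, 5)
  obs_i <- session_observables(lab, centroids = cen, K = K)
  perm <- c(2L, 3L, 1L)
  obs_j <- session_observables(perm[lab], centroids = cen[order(perm), ],
                               K = K)
  for (ob in c("centroid", "coverage", "frequency", "lifespan", "transition")) {
    d <- session_discrepancy(obs_i, obs_j, ob)
    expect_equal(d$value, 0, tolerance = 1e-12, info = ob)
  }

  # symmetry on generic pairs
  lab2 <- sample.int(K, 40, replace = TRUE)
  cen2 <- matrix(rnorm(K * 5), K, 5)
  obs_k <- session_observables(lab2, centroids = cen2, K = K)
  for (ob in c("centroid", "coverage", "frequency", "lifespan", "transition")) {
    expect_equal(session_discrepancy(obs_i, obs_k, ob)$value,
                 session_discrepancy(obs_k, obs_i, ob)$value,
                 tolerance = 1e-12, info = ob)
  }
  expect_error(session_discrepancy(obs_i,
                                   session_observables(c(1, 2), diag(2), K = 2),
                                   "centroid"),
               "different K")
})

test_that("hand-built K = 2 pair reproduces the full hand pipeline", {
  # session i: labels 1,1,2,2,2,1; centroids along e1 and e2
  obs_i <- session_observables(c(1, 1, 2, 2, 2, 1),
                               centroids = rbind(c(1, 0), c(0, 1)), K = 2)
  # session j: labels 1,1,1,2,2,2; centroids parallel to i's but swapped
  obs_j <- session_observables(c(1, 1, 1, 2, 2, 2),
                               centroids = rbind(c(0, 2), c(3, 0)), K = 2)
  res <- pair_discrepancies(obs_i, obs_j, mode = "cosine")
  expect_identical(res$matching$permutation, c(2L, 1L))
  # hand values: matched cosines are both 1 -> centroid 0; coverage
  # (1/2,1/2) vs (1/2,1/2) -> 0; frequency (2/6,1/6) vs (1/6,1/6) -> 1/6;
  # lifespan (1.5,3) vs (3,3) -> 1.5; transition: P_i = [[0,1],[1,0]], while
  # session j has the single change 1->2, so P_j = [[0,1],[0,0]] with a zero
  # row for its state 2; aligned by the swap it becomes [[0,0],[1,0]], and
  # only the (1,2) entry differs from P_i -> Frobenius = 1
  expect_equal(unname(res$values),
               c(0, 0, 1 / 6, 1.5, 1), tolerance = 1e-12)
})

test_that("euclidean mode threads through matching and all observables", {
  set.seed(57)
  K <- 3
  obs_a <- session_observables(sample.int(K, 30, TRUE),
                               centroids = matrix(rnorm(K * 4), K, 4), K = K)
  obs_b <- session_observables(sample.int(K, 30, TRUE),
                               centroids = matrix(rnorm(K * 4), K, 4), K = K)
  rc <- pair_discrepancies(obs_a, obs_b, mode = "cosine")
  re <- pair_discrepancies(obs_a, obs_b, mode = "euclidean")
  # euclidean centroid value is the mean squared distance under its matching
  d_direct <- mean(sapply(1:K, function(l) {
    sum((obs_a$centroids[l, ] - obs_b$centroids[re$matching$permutation[l], ])^2)
  }))
  expect_equal(unname(re$values["centroid"]), d_direct, tolerance = 1e-12)
  # the matchings may differ; if they do, downstream values differ too
  if (!identical(rc$matching$permutation, re$matching$permutation)) {
    expect_false(isTRUE(all.equal(rc$values[-1], re$values[-1])))
  }
})
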