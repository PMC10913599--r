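test_that("cosine_similarity handles the canonical cases", {
  expect_equal(cosine_similarity(c(1, 0), c(1, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(-1, 0)), -1)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero vector")
})

test_that("all seven methods recover well-separated blobs and are deterministic", {
  b <- make_blobs(seed = 3)
  methods <- c("kmeans", "kmedoids", "ward", "aahc", "taahc",
               "bisecting_kmeans", "gmm")
  for (m in methods) {
    p1 <- estimate_states(b$X, 2, m, seed = 42)
    p2 <- estimate_states(b$X, 2, m, seed = 42)
    expect_true(labels_agree(p1$labels, b$truth, 2), info = m)
    expect_identical(p1$labels, p2$labels)           # determinism contract
    expect_identical(p1$centroids, p2$centroids)
    # mean-centroid invariant (medoid invariant checked separately)
    if (m %in% c("kmeans", "ward", "aahc", "taahc", "bisecting_kmeans")) {
      for (k in 1:2) {
        expect_equal(p1$centroids[k, ],
                     colMeans(b$X[p1$labels == k, , drop = FALSE]),
                     tolerance = 1e-12, info = m)
      }
    }
  }
})

test_that("k-medoids centroids are data rows; T = K gives singletons", {
  X <- matrix(c(0, 0, 5, 5, -4, 3), 3, 2, byrow = TRUE)
  p <- estimate_states(X, 3, "kmedoids", seed = 1)
  expect_setequal(p$labels, 1:3)
  # each centroid is exactly one of the rows
  for (k in 1:3) {
    expect_true(any(apply(X, 1, function(r) identical(r, p$centroids[k, ]))))
  }

  b <- make_blobs(seed = 9)
  pm <- estimate_states(b$X, 2, "kmedoids", seed = 5)
  for (k in 1:2) {
    expect_true(any(apply(b$X, 1, function(r) all(r == pm$centroids[k, ]))))
  }
})

test_that("infeasible K and bad inputs error", {
  X <- rbind(c(1, 2), c(1, 2), c(3, 4))
  expect_error(estimate_states(X, 3, "kmeans"), "infeasible K")
  expect_error(estimate_states(X, 1, "kmeans"), "2 <= K <= T")
  expect_error(estimate_states(matrix(c(1, NA, 2, 3), 2, 2), 2, "kmeans"),
               "finite")
})

test_that("k-means RSS is monotone non-increasing and near the global optimum", {
  eq <- logical(20)
  for (s in seq_len(20)) {
    b <- make_blobs(n_per = 6L, seed = s)   # T = 12: exhaustive search feasible
    p <- estimate_states(b$X, 2, "kmeans", seed = s)
    trace <- attr(p, "rss_trace")
    expect_true(all(diff(trace) <= 1e-9))
    rss <- trace[length(trace)]
    opt <- brute_force_rss_k2(b$X)
    expect_gte(rss, opt - 1e-8)
    eq[s] <- abs(rss - opt) < 1e-6
  }
  expect_gte(mean(eq), 0.9)
})

test_that("random instances: k-means never beats the exhaustive optimum", {
  for (s in 1:10) {
    set.seed(100 + s)
    X <- matrix(rnorm(20), 10, 2)
    p <- estimate_states(X, 2, "kmeans", seed = s)
    rss <- attr(p, "rss_trace")[length(attr(p, "rss_trace"))]
    expect_gte(rss, brute_force_rss_k2(X) - 1e-8)
  }
})

test_that("AAHC/TAAHC atomize exactly T - K times", {
  set.seed(7)
  X <- matrix(rnorm(60), 30, 2) + 5   # offset avoids zero-norm rows
  for (m in c("aahc", "taahc")) {
    for (K in c(2, 5)) {
      p <- estimate_states(X, K, m, seed = 1)
      expect_identical(attr(p, "atomize_steps"), 30L - as.integer(K))
      expect_setequal(unique(p$labels), seq_len(K))
    }
  }
})

test_that("worst_cluster_gev matches direct evaluation and documented ties", {
  # cluster 1 parallel to its centroid (GEV > 0), cluster 2 orthogonal (GEV 0)
  X <- rbind(c(2, 0), c(4, 0), c(0, 3), c(0, -3))
  part <- state_partition(c(1, 1, 2, 2), rbind(c(1, 0), c(1, 0)))
  expect_identical(worst_cluster_gev(X, part, sigma = rep(1, 4)), 2L)

  # 4-point instance vs in-test brute force of the GEV formula
  set.seed(11)
  X2 <- matrix(rnorm(8), 4, 2) + 3
  lab <- c(1, 2, 1, 2)
  cen <- rbind(colMeans(X2[c(1, 3), ]), colMeans(X2[c(2, 4), ]))
  part2 <- state_partition(lab, cen)
  gev_direct <- sapply(1:2, function(k) {
    num <- 0
    for (t in 1:4) {
      if (lab[t] == k) {
        cs <- sum(X2[t, ] * cen[k, ]) /
          (sqrt(sum(X2[t, ]^2)) * sqrt(sum(cen[k, ]^2)))
        num <- num + cs^2
      }
    }
    num / 4
  })
  expect_identical(worst_cluster_gev(X2, part2, sigma = rep(1, 4)),
                   which.min(gev_direct))

  # exact tie -> smallest index
  Xt <- rbind(c(1, 0), c(0, 1))
  pt <- state_partition(c(1, 2), rbind(c(1, 0), c(0, 1)))
  expect_identical(worst_cluster_gev(Xt, pt, sigma = rep(1, 2)), 1L)
})

test_that("worst_cluster_crs: singletons lose to coherent clusters", {
  # singleton has CRS = cos(x, x) = 1; m parallel points have CRS = m
  X <- rbind(c(5, 5), c(1, 1), c(2, 2), c(3, 3))
  part <- state_partition(c(1, 2, 2, 2), rbind(c(5, 5), c(2, 2)))
  expect_identical(worst_cluster_crs(X, part), 1L)

  # 3-point instance vs direct evaluation
  X3 <- rbind(c(1, 0.2), c(0.9, -0.1), c(0.1, 1))
  lab3 <- c(1, 1, 2)
  cen3 <- rbind(colMeans(X3[1:2, ]), X3[3, , drop = FALSE])
  crs_direct <- sapply(1:2, function(k) {
    sum(sapply(which(lab3 == k), function(t) {
      sum(X3[t, ] * cen3[k, ]) /
        (sqrt(sum(X3[t, ]^2)) * sqrt(sum(cen3[k, ]^2)))
    }))
  })
  expect_identical(worst_cluster_crs(X3, state_partition(lab3, cen3)),
                   which.min(crs_direct))
})

test_that("atomize_reassign dissolves one cluster and reassigns by cosine", {
  # cluster 3's two points are parallel to the centroids of clusters 1 and 2
  X <- rbind(c(1, 0), c(0.9, 0), c(0, 1), c(0, 1.2), c(2, 0), c(0, 3))
  part <- state_partition(c(1, 1, 2, 2, 3, 3),
                          rbind(colMeans(X[1:2, ]), colMeans(X[3:4, ]),
                                colMeans(X[5:6, ])))
  out <- atomize_reassign(X, part, worst = 3L)
  expect_identical(out$K, 2L)
  expect_identical(out$labels, c(1L, 1L, 2L, 2L, 1L, 2L))
  expect_equal(out$centroids[1, ], colMeans(X[c(1, 2, 5), ]))
  expect_equal(out$centroids[2, ], colMeans(X[c(3, 4, 6), ]))

  expect_error(atomize_reassign(X, state_partition(rep(1, 6),
                                                   matrix(colMeans(X), 1)), 1),
               "only one cluster")
})

test_that("atomize_reassign matches an independent step simulation", {
  set.seed(21)
  X <- matrix(rnorm(12), 6, 2) + 4
  lab <- c(1, 1, 2, 2, 3, 3)
  cen <- rbind(colMeans(X[1:2, ]), colMeans(X[3:4, ]), colMeans(X[5:6, ]))
  part <- state_partition(lab, cen)
  worst <- 2L
  # independent simulation with plain loops
  survivors <- cen[-worst, , drop = FALSE]
  new_lab <- ifelse(lab == 1, 1L, ifelse(lab == 3, 2L, NA))
  for (t in which(lab == worst)) {
    cs <- sapply(1:2, function(k) {
      sum(X[t, ] * survivors[k, ]) /
        (sqrt(sum(X[t, ]^2)) * sqrt(sum(survivors[k, ]^2)))
    })
    new_lab[t] <- which.max(cs)
  }
  out <- atomize_reassign(X, part, worst)
  expect_identical(out$labels, as.integer(new_lab))
  for (k in 1:2) {
    expect_equal(out$centroids[k, ], colMeans(X[new_lab == k, , drop = FALSE]))
  }
})

test_that("gev_total attains its extremes and matches hand computation", {
  # every point parallel to its centroid -> 1
  X <- rbind(c(1, 0), c(2, 0), c(0, 1), c(0, 5))
  part <- state_partition(c(1, 1, 2, 2), rbind(c(3, 0), c(0, 1)))
  expect_equal(gev_total(X, part, sigma = rep(1, 4)), 1)

  # every point orthogonal to its centroid -> 0
  part0 <- state_partition(c(1, 1, 2, 2), rbind(c(0, 1), c(1, 0)))
  expect_equal(gev_total(X, part0, sigma = rep(1, 4)), 0)

  # hand-computed toy: cos^2 = (1, 1, 0.8, 0.9) -> GEV_total = 0.925
  Xh <- rbind(c(1, 0), c(2, 0), c(0, 1), c(1, 1))
  ph <- state_partition(c(1, 1, 2, 2), rbind(c(1.5, 0), c(0.5, 1)))
  expect_equal(gev_total(Xh, ph, sigma = rep(1, 4)), 0.925, tolerance = 1e-12)

  # sigma = 1 short-circuit equals mean squared cosine to own centroid
  set.seed(31)
  Xr <- matrix(rnorm(40), 10, 4)
  Xr <- Xr / sqrt(rowSums(Xr^2))
  pr <- estimate_states(Xr, 3, "kmeans", seed = 2)
  direct <- mean(sapply(seq_len(10), function(t) {
    cosine_similarity(Xr[t, ], pr$centroids[pr$labels[t], ])^2
  }))
  expect_equal(gev_total(Xr, pr, sigma = rep(1, 10)), direct,
               tolerance = 1e-12)
})

test_that("wcss definition and monotonicity in K for nested bisecting runs", {
  X <- rbind(c(0, 0), c(2, 0))
  part <- state_partition(c(1, 1), matrix(c(1, 0), 1))
  expect_equal(wcss(X, part), 2)   # 1 + 1
  exact <- state_partition(1:2, X)
  expect_equal(wcss(X, exact), 0)

  set.seed(41)
  Xr <- matrix(rnorm(100), 50, 2)
  w <- sapply(2:6, function(K) {
    wcss(Xr, estimate_states(Xr, K, "bisecting_kmeans", seed = 7))
  })
  expect_true(all(diff(w) <= 1e-9))
})

test_that("GMM log-likelihood is non-decreasing and centroids are the means", {
  b <- make_blobs(n_per = 15L, seed = 6)
  p <- estimate_states(b$X, 2, "gmm", seed = 8)
  ll <- attr(p, "loglik_trace")
  expect_true(all(diff(ll) >= -1e-8))
  raw_means <- attr(p, "gmm_params")$means
  for (k in 1:2) {
    gaps <- apply(raw_means, 1, function(mu) max(abs(mu - p$centroids[k, ])))
    expect_lt(min(gaps), 1e-12)  # each centroid is one of the component means
  }
})
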