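# two well-separated Gaussian blobs in 2-D; separation >> spread so the
# optimal 2-clustering is unambiguous
make_blobs <- function(n_per = 10L, sep = 10, sd = 0.5, seed = 1L) {
  set.seed(seed)
  X <- rbind(
    matrix(stats::rnorm(2 * n_per, mean = sep / 2, sd = sd), n_per, 2),
    matrix(stats::rnorm(2 * n_per, mean = -sep / 2, sd = sd), n_per, 2)
  )
  list(X = X, truth = rep(1:2, each = n_per))
}

# agreement of two labelings up to permutation of labels (small K)
labels_agree <- function(a, b, K) {
  perms <- statedyn:::perms_lex(K)
  any(apply(perms, 1L, function(p) all(p[a] == b)))
}

# exhaustive search over all 2-cluster partitions: minimal k-means RSS
brute_force_rss_k2 <- function(X) {
  T_ <- nrow(X)
  best <- Inf
  for (mask in 1:(2^(T_ - 1L) - 1L)) {  # point 1 always in cluster 1
    in1 <- c(TRUE, as.logical(bitwAnd(mask, 2^(0:(T_ - 2L)))))
    if (!any(!in1)) next
    rss <- sum(scale(X[in1, , drop = FALSE], scale = FALSE)^2) +
      sum(scale(X[!in1, , drop = FALSE], scale = FALSE)^2)
    best <- min(best, rss)
  }
  best
}

# independent brute-force matcher: recursive permutation enumeration written
# separately from the package's lexicographic generator
oracle_best_matching <- function(C1, C2, mode = "cosine") {
  K <- nrow(C1)
  score_pair <- function(i, j) {
    if (mode == "cosine") {
      sum(C1[i, ] * C2[j, ]) / (sqrt(sum(C1[i, ]^2)) * sqrt(sum(C2[j, ]^2)))
    } else {
      sum((C1[i, ] - C2[j, ])^2)
    }
  }
  best_perm <- NULL
  best_val <- if (mode == "cosine") -Inf else Inf
  rec <- function(prefix, remaining) {
    if (length(remaining) == 0L) {
      val <- mean(mapply(score_pair, seq_len(K), prefix))
      better <- if (mode == "cosine") val > best_val else val < best_val
      if (better) {
        best_val <<- val
        best_perm <<- prefix
      }
      return(invisible())
    }
    for (r in remaining) rec(c(prefix, r), setdiff(remaining, r))
  }
  rec(integer(0), seq_len(K))
  list(permutation = best_perm, value = best_val)
}

# second algebraic form of the ND statistic, written independently of the
# package: (N_s - 1) * sum(between) / ((N_p - 1) * sum(within))
nd_second_form <- function(D, Np, Ns) {
  cell <- function(p, s) (p - 1L) * Ns + s
  num <- 0
  for (s in seq_len(Ns)) for (p in seq_len(Np)) for (pp in seq_len(p - 1L)) {
    num <- num + D[cell(p, s), cell(pp, s)]
  }
  den <- 0
  for (p in seq_len(Np)) for (s in seq_len(Ns)) for (ss in seq_len(s - 1L)) {
    den <- den + D[cell(p, s), cell(p, ss)]
  }
  (Ns - 1) * num / ((Np - 1) * den)
}

# tiny study: N_p x N_s sessions as a payload list of plain numbers with
# absolute-difference dissimilarity (for ND unit tests)
scalar_grid <- function(values) values

write_session_csv <- function(X, sep = ",") {
  f <- tempfile(fileext = ".csv")
  writeLines(apply(X, 1L, paste, collapse = sep), f)
  f
}
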