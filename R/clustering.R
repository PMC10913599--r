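#' Cosine similarity between two vectors
#'
#' `corr(u, v) = <u, v> / (||u|| ||v||)`, the similarity used throughout for
#' comparing volumes with state centroids and centroids across sessions.
#'
#' @param u,v Numeric vectors of equal length with positive norm.
#' @return A number in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

# rows of X against a single centroid; X assumed pre-normalized if xn given
row_cosines <- function(X, centre) {
  nc <- sqrt(sum(centre^2))
  if (nc == 0) stop("cosine similarity undefined for a zero-norm centroid")
  rn <- sqrt(rowSums(X^2))
  if (any(rn == 0)) stop("cosine similarity undefined: zero-norm data row")
  as.vector(X %*% centre) / (rn * nc)
}

#' Construct a state partition
#'
#' A partition of a session's T volumes into K discrete states: integer labels
#' `1..K` per volume plus the K centroid vectors. For all methods except
#' K-medoids and the Gaussian mixture, each centroid is the mean of its
#' member volumes; for K-medoids each centroid is a data row (the medoid).
#'
#' @param labels Integer vector of length T with values in 1..K; every state
#'   must be non-empty.
#' @param centroids K x N numeric matrix of state centroids.
#' @param method Clustering method name.
#' @param seed Seed used, or NULL.
#' @return An object of class `state_partition`.
#' @export
state_partition <- function(labels, centroids, method = "manual", seed = NULL) {
  labels <- as.integer(labels)
  centroids <- as.matrix(centroids)
  K <- nrow(centroids)
  if (any(labels < 1L | labels > K))
    stop("labels must lie in 1..K with K = nrow(centroids)")
  if (length(unique(labels)) != K)
    stop("every state in 1..", K, " must be non-empty at construction time")
  structure(list(labels = labels, centroids = centroids, K = K,
                 method = method, seed = seed),
            class = "state_partition")
}

#' @export
print.state_partition <- function(x, ...) {
  cat(sprintf("<state_partition> method=%s K=%d T=%d N=%d\n",
              x$method, x$K, length(x$labels), ncol(x$centroids)))
  invisible(x)
}

#' Estimate K discrete states from a session's volumes
#'
#' Clusters the T volumes (rows) of `X` into K states with one of seven
#' methods:
#' \describe{
#'   \item{kmeans}{k-means++ initialization, then alternating nearest-centroid
#'     assignment and mean update until the residual sum of squares changes by
#'     less than 1e-5 (absolute).}
#'   \item{kmedoids}{k-means++ style initialization on data points; medoid of
#'     each cluster is the member minimizing the summed Euclidean distance to
#'     the other members; stops when the medoid set repeats.}
#'   \item{ward}{bottom-up agglomeration under Ward's minimum-variance
#'     criterion, cut at K clusters.}
#'   \item{aahc}{atomize-and-agglomerate hierarchical clustering: start from T
#'     singletons; repeatedly dissolve the cluster with the smallest global
#'     explained variance (GEV) and reassign each freed volume to the
#'     surviving cluster with the highest cosine similarity.}
#'   \item{taahc}{the topographic variant: the worst cluster minimizes the sum
#'     of cosine similarities of members to their centroid.}
#'   \item{bisecting_kmeans}{start from one cluster; repeatedly split the
#'     cluster with the largest within-cluster sum of squared errors by
#'     2-means.}
#'   \item{gmm}{Gaussian mixture fitted by EM (full covariances, K-means
#'     initialization); hard labels by maximum posterior component weight,
#'     centroids are the component means.}
#' }
#'
#' States are relabeled 1..K by order of first appearance in time, so the
#' output is deterministic given (X, K, method, seed).
#'
#' @param X T x N numeric matrix of volumes.
#' @param K Number of states, 2 <= K <= T.
#' @param method One of the seven method names above.
#' @param seed Integer seed controlling all method randomness.
#' @param n_init Number of independent k-means++ restarts for `kmeans` (the
#'   best final RSS wins); also used by the 2-means splits of
#'   `bisecting_kmeans` and the K-means initialization of `gmm`.
#' @return A [state_partition()]. K-means solutions carry the per-iteration
#'   RSS trace in `attr(, "rss_trace")` (of the winning restart); the GMM
#'   carries `attr(, "loglik_trace")`.
#' @export
estimate_states <- function(X, K,
                            method = c("kmeans", "kmedoids", "ward", "aahc",
                                       "taahc", "bisecting_kmeans", "gmm"),
                            seed = 1L, n_init = 10L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  T_ <- nrow(X)
  if (!all(is.finite(X))) stop("X must be finite")
  if (K < 2L || K > T_) stop("K must satisfy 2 <= K <= T")
  n_distinct <- nrow(unique(X))
  if (K > n_distinct)
    stop("infeasible K: ", K, " states requested but only ", n_distinct,
         " distinct volumes")
  if (!is.null(seed)) set.seed(as.integer(seed))
  fit <- switch(method,
    kmeans = kmeans_fit(X, K, n_init = n_init),
    kmedoids = kmedoids_fit(X, K),
    ward = ward_fit(X, K),
    aahc = aahc_fit(X, K, criterion = "gev"),
    taahc = aahc_fit(X, K, criterion = "crs"),
    bisecting_kmeans = bisecting_fit(X, K, n_init = n_init),
    gmm = gmm_fit(X, K, n_init = n_init)
  )
  part <- finalize_partition(fit$labels, fit$centroids, method, seed)
  for (a in names(fit$attrs)) attr(part, a) <- fit$attrs[[a]]
  part
}

# relabel states 1..K by first appearance in time; permute centroids to match
finalize_partition <- function(labels, centroids, method, seed) {
  order_seen <- unique(labels)
  new_of_old <- integer(nrow(centroids))
  new_of_old[order_seen] <- seq_along(order_seen)
  state_partition(new_of_old[labels], centroids[order_seen, , drop = FALSE],
                  method = method, seed = seed)
}

# squared Euclidean distances from every row of X to every row of C
sqdist_to_centroids <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
  d2[d2 < 0] <- 0
  d2
}

# k-means++ seeding: returns indices of K chosen rows
kmeanspp_indices <- function(X, K) {
  T_ <- nrow(X)
  idx <- integer(K)
  idx[1L] <- sample.int(T_, 1L)
  d2 <- rowSums((X - rep(X[idx[1L], ], each = T_))^2)
  for (k in seq_len(K - 1L) + 1L) {
    d2[idx[seq_len(k - 1L)]] <- 0
    if (all(d2 == 0)) {           # all remaining points coincide with centers
      cand <- setdiff(seq_len(T_), idx[seq_len(k - 1L)])
      idx[k] <- cand[1L]
    } else {
      idx[k] <- sample.int(T_, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums((X - rep(X[idx[k], ], each = T_))^2))
  }
  idx
}

# n_init independent k-means++ restarts; the solution with the lowest final
# RSS is kept (the convention of the reference implementation)
kmeans_fit <- function(X, K, max_iter = 300L, tol = 1e-5, n_init = 10L) {
  best <- NULL
  for (i in seq_len(n_init)) {
    fit <- kmeans_single(X, K, max_iter, tol)
    rss <- fit$attrs$rss_trace[length(fit$attrs$rss_trace)]
    if (is.null(best) || rss < best_rss) {
      best <- fit
      best_rss <- rss
    }
  }
  best
}

kmeans_single <- function(X, K, max_iter = 300L, tol = 1e-5) {
  C <- X[kmeanspp_indices(X, K), , drop = FALSE]
  rss_prev <- Inf
  rss_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    labels <- max.col(-sqdist_to_centroids(X, C), ties.method = "first")
    # empty-cluster remedy: reseed with the point farthest from its centroid
    for (k in which(tabulate(labels, K) == 0L)) {
      d_self <- rowSums((X - C[labels, , drop = FALSE])^2)
      far <- which.max(d_self)
      labels[far] <- k
    }
    C <- centroid_means(X, labels, K)
    rss <- sum((X - C[labels, , drop = FALSE])^2)
    rss_trace <- c(rss_trace, rss)
    if (abs(rss_prev - rss) < tol) {
      return(list(labels = labels, centroids = C,
                  attrs = list(rss_trace = rss_trace, iterations = it)))
    }
    rss_prev <- rss
  }
  stop("k-means failed to converge within ", max_iter,
       " iterations (last RSS = ", signif(rss_prev, 8), ")")
}

centroid_means <- function(X, labels, K) {
  C <- matrix(0, K, ncol(X))
  for (k in seq_len(K)) {
    members <- labels == k
    C[k, ] <- colMeans(X[members, , drop = FALSE])
  }
  C
}

kmedoids_fit <- function(X, K, max_iter = 300L) {
  D <- as.matrix(stats::dist(X))  # Euclidean, for medoid updates
  med <- sort(kmeanspp_indices(X, K))
  seen <- list()
  for (it in seq_len(max_iter)) {
    labels <- max.col(-D[, med, drop = FALSE], ties.method = "first")
    for (k in which(tabulate(labels, K) == 0L)) labels[med[k]] <- k
    new_med <- med
    for (k in seq_len(K)) {
      members <- which(labels == k)
      cost <- colSums(D[members, members, drop = FALSE])
      new_med[k] <- members[which.min(cost)]
    }
    key <- paste(sort(new_med), collapse = ",")
    if (identical(new_med, med) || key %in% seen) {
      labels <- max.col(-D[, new_med, drop = FALSE], ties.method = "first")
      for (k in which(tabulate(labels, K) == 0L)) labels[new_med[k]] <- k
      return(list(labels = labels,
                  centroids = X[new_med, , drop = FALSE],
                  attrs = list(medoids = new_med, iterations = it)))
    }
    seen[[length(seen) + 1L]] <- key
    med <- new_med
  }
  stop("k-medoids failed to converge within ", max_iter, " iterations")
}

ward_fit <- function(X, K) {
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  labels <- stats::cutree(hc, k = K)
  list(labels = labels, centroids = centroid_means(X, labels, K),
       attrs = list())
}

bisecting_fit <- function(X, K, n_init = 10L) {
  labels <- rep(1L, nrow(X))
  n_clusters <- 1L
  while (n_clusters < K) {
    sse <- vapply(seq_len(n_clusters), function(k) {
      members <- labels == k
      sum(scale(X[members, , drop = FALSE], scale = FALSE)^2)
    }, numeric(1))
    target <- which.max(sse)  # ties -> smallest index
    members <- which(labels == target)
    sub <- kmeans_fit(X[members, , drop = FALSE], 2L, n_init = n_init)
    n_clusters <- n_clusters + 1L
    labels[members[sub$labels == 2L]] <- n_clusters
  }
  list(labels = labels, centroids = centroid_means(X, labels, K),
       attrs = list())
}

## ---- AAHC / TAAHC ---------------------------------------------------------

# internal partition state for agglomeration: list of member-index vectors
aahc_fit <- function(X, K, criterion = c("gev", "crs")) {
  criterion <- match.arg(criterion)
  T_ <- nrow(X)
  rn <- sqrt(rowSums(X^2))
  if (any(rn == 0)) stop("AAHC/TAAHC undefined: zero-norm data row")
  sigma <- gfp(X)
  sig2_total <- sum(sigma^2)
  clusters <- as.list(seq_len(T_))
  centroids <- X
  crit <- cluster_criterion_all(X, clusters, centroids, criterion, sigma,
                                sig2_total, rn)
  steps <- 0L
  while (length(clusters) > K) {
    worst <- which.min(crit)  # ties -> smallest cluster index
    res <- atomize_step(X, clusters, centroids, worst, rn)
    clusters <- res$clusters
    centroids <- res$centroids
    crit <- crit[-worst]
    for (k in res$changed) {
      crit[k] <- cluster_criterion_one(X, clusters[[k]], centroids[k, ],
                                       criterion, sigma, sig2_total, rn)
    }
    steps <- steps + 1L
  }
  labels <- integer(T_)
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  list(labels = labels,
       centroids = centroids,
       attrs = list(atomize_steps = steps))
}

# dissolve cluster `worst`; reassign each member to the surviving cluster with
# maximal cosine similarity (evaluated against pre-atomization centroids);
# recompute centroids of clusters that gained members
atomize_step <- function(X, clusters, centroids, worst, rn) {
  members <- clusters[[worst]]
  clusters <- clusters[-worst]
  centroids <- centroids[-worst, , drop = FALSE]
  cn <- sqrt(rowSums(centroids^2))
  sims <- tcrossprod(X[members, , drop = FALSE], centroids) /
    outer(rn[members], cn)
  dest <- max.col(sims, ties.method = "first")
  changed <- sort(unique(dest))
  for (i in seq_along(members)) {
    k <- dest[i]
    clusters[[k]] <- c(clusters[[k]], members[i])
  }
  for (k in changed) {
    centroids[k, ] <- colMeans(X[clusters[[k]], , drop = FALSE])
  }
  list(clusters = clusters, centroids = centroids, changed = changed)
}

cluster_criterion_all <- function(X, clusters, centroids, criterion, sigma,
                                  sig2_total, rn) {
  vapply(seq_along(clusters), function(k) {
    cluster_criterion_one(X, clusters[[k]], centroids[k, ], criterion, sigma,
                          sig2_total, rn)
  }, numeric(1))
}

cluster_criterion_one <- function(X, members, centre, criterion, sigma,
                                  sig2_total, rn) {
  nc <- sqrt(sum(centre^2))
  if (nc == 0) stop("zero-norm centroid in agglomeration")
  cors <- as.vector(X[members, , drop = FALSE] %*% centre) / (rn[members] * nc)
  if (criterion == "gev") {
    sum(cors^2 * sigma[members]^2) / sig2_total
  } else {
    sum(cors)
  }
}

## ---- cluster quality ------------------------------------------------------

#' Global field power of each volume
#'
#' The per-volume spatial standard deviation across ROIs (population divisor),
#' used as the weight in the global explained variance. After a treatment
#' ending in global signal removal it is identically 1.
#'
#' @param X T x N matrix.
#' @return Numeric vector of length T.
#' @export
gfp <- function(X) {
  X <- as.matrix(X)
  mu <- rowMeans(X)
  sqrt(rowMeans((X - mu)^2))
}

# per-cluster GEV vector for a partition
gev_by_cluster <- function(X, part, sigma = NULL) {
  X <- as.matrix(X)
  if (is.null(sigma)) sigma <- gfp(X)
  stopifnot(length(sigma) == nrow(X))
  if (any(sigma <= 0)) stop("GEV requires sigma_t > 0 for all volumes")
  rn <- sqrt(rowSums(X^2))
  if (any(rn == 0)) stop("GEV undefined: zero-norm data row")
  sig2_total <- sum(sigma^2)
  vapply(seq_len(part$K), function(k) {
    members <- which(part$labels == k)
    if (length(members) == 0L)
      stop("contract violation: empty cluster ", k)
    cluster_criterion_one(X, members, part$centroids[k, ], "gev", sigma,
                          sig2_total, rn)
  }, numeric(1))
}

#' Index of the worst cluster by global explained variance
#'
#' Returns the cluster with the smallest GEV contribution
#' `GEV_l = sum_t delta(L_t, l) corr(x_t, c_l)^2 sigma_t^2 / sum_t sigma_t^2`;
#' ties are broken towards the smallest index. This is the atomization target
#' of AAHC.
#'
#' @param X T x N matrix.
#' @param part A [state_partition()].
#' @param sigma Per-volume global field power; defaults to [gfp()] of `X`.
#' @return Integer cluster index.
#' @export
worst_cluster_gev <- function(X, part, sigma = NULL) {
  which.min(gev_by_cluster(X, part, sigma))
}

#' Index of the worst cluster by summed correlation (TAAHC criterion)
#'
#' Returns the minimizer of `CRS(l) = sum_t delta(L_t, l) corr(x_t, c_l)`;
#' ties are broken towards the smallest index.
#'
#' @inheritParams worst_cluster_gev
#' @return Integer cluster index.
#' @export
worst_cluster_crs <- function(X, part) {
  X <- as.matrix(X)
  rn <- sqrt(rowSums(X^2))
  if (any(rn == 0)) stop("CRS undefined: zero-norm data row")
  crs <- vapply(seq_len(part$K), function(k) {
    members <- which(part$labels == k)
    if (length(members) == 0L)
      stop("contract violation: empty cluster ", k)
    cluster_criterion_one(X, members, part$centroids[k, ], "crs", NULL, NULL, rn)
  }, numeric(1))
  which.min(crs)
}

#' Dissolve one cluster and reassign its members (one AAHC/TAAHC step)
#'
#' The `worst` cluster is atomized: each of its member volumes is reassigned
#' to the surviving cluster whose centroid has the highest cosine similarity
#' with the volume, and surviving centroids are then recomputed as member
#' means. The result has exactly one cluster fewer.
#'
#' @param X T x N matrix.
#' @param part A [state_partition()] with at least 2 clusters.
#' @param worst Index of the cluster to atomize.
#' @return A [state_partition()] with `part$K - 1` clusters.
#' @export
atomize_reassign <- function(X, part, worst) {
  if (part$K < 2L) stop("cannot atomize: only one cluster present")
  X <- as.matrix(X)
  rn <- sqrt(rowSums(X^2))
  if (any(rn == 0)) stop("cosine reassignment undefined: zero-norm data row")
  clusters <- lapply(seq_len(part$K), function(k) which(part$labels == k))
  res <- atomize_step(X, clusters, part$centroids, worst, rn)
  labels <- integer(nrow(X))
  for (k in seq_along(res$clusters)) labels[res$clusters[[k]]] <- k
  state_partition(labels, res$centroids, method = part$method, seed = part$seed)
}

#' Total global explained variance of a partition
#'
#' `GEV_total = sum_l GEV_l`, the GFP-weighted fraction of variance explained
#' by assigning each volume to its state centroid via squared cosine
#' similarity. When `sigma` is identically 1 (any treatment ending in global
#' signal removal) this reduces to `mean_t corr(x_t, c_{L_t})^2`.
#'
#' @inheritParams worst_cluster_gev
#' @return A fraction in \[0, 1\].
#' @export
gev_total <- function(X, part, sigma = NULL) {
  sum(gev_by_cluster(X, part, sigma))
}

#' Within-cluster sum of squares of a partition
#'
#' `WCSS = sum_t || x_t - c_{L_t} ||^2`. Smaller is better; complements GEV,
#' which only measures directional agreement.
#'
#' @inheritParams worst_cluster_gev
#' @return Non-negative number.
#' @export
wcss <- function(X, part) {
  X <- as.matrix(X)
  sum((X - part$centroids[part$labels, , drop = FALSE])^2)
}

## ---- Gaussian mixture -----------------------------------------------------

gmm_fit <- function(X, K, max_iter = 300L, tol = 1e-6, reg = 1e-6,
                    n_init = 10L) {
  T_ <- nrow(X); N <- ncol(X)
  km <- kmeans_fit(X, K, n_init = n_init)
  resp <- matrix(0, T_, K)
  resp[cbind(seq_len(T_), km$labels)] <- 1
  params <- gmm_mstep(X, resp, reg)
  ll_prev <- -Inf
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    logdens <- vapply(seq_len(K), function(k) {
      log(params$weights[k]) + mvn_logpdf(X, params$means[k, ], params$covs[[k]])
    }, numeric(T_))
    m <- apply(logdens, 1L, max)
    lse <- m + log(rowSums(exp(logdens - m)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(logdens - lse)
    if (abs(ll - ll_prev) < tol) {
      labels <- max.col(logdens, ties.method = "first")
      if (length(unique(labels)) < K)
        stop("GMM hard assignment left a component empty; reduce K or noise")
      return(list(labels = labels, centroids = params$means,
                  attrs = list(loglik_trace = ll_trace,
                               gmm_params = params, iterations = it)))
    }
    ll_prev <- ll
    params <- gmm_mstep(X, resp, reg)
  }
  stop("GMM EM failed to converge within ", max_iter,
       " iterations (best log-likelihood = ", signif(ll_prev, 8), ")")
}

gmm_mstep <- function(X, resp, reg) {
  T_ <- nrow(X); N <- ncol(X); K <- ncol(resp)
  nk <- colSums(resp) + 10 * .Machine$double.eps
  weights <- nk / T_
  means <- crossprod(resp, X) / nk
  covs <- lapply(seq_len(K), function(k) {
    Xc <- X - rep(means[k, ], each = T_)
    S <- crossprod(Xc * resp[, k], Xc) / nk[k]
    S + diag(reg, N)
  })
  list(weights = weights, means = means, covs = covs)
}

mvn_logpdf <- function(X, mu, Sigma) {
  N <- ncol(X)
  ch <- chol(Sigma)
  Xc <- t(X) - mu
  z <- backsolve(ch, Xc, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * N * log(2 * pi)
}
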