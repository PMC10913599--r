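## Matching the K states of one session onto the K states of another, and the
## per-observable discrepancy measures computed after matching.

# all permutations of 1..n in lexicographic row order (cached; n <= 8 in use)
perms_lex <- function(n) {
  cache <- get0("perm_cache", envir = .statedyn_env, ifnotfound = list())
  key <- as.character(n)
  if (!is.null(cache[[key]])) return(cache[[key]])
  gen <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L, 1L))
    out <- vector("list", length(v))
    for (i in seq_along(v)) {
      sub <- gen(v[-i])
      out[[i]] <- cbind(v[i], sub)
    }
    do.call(rbind, out)
  }
  p <- gen(seq_len(n))
  cache[[key]] <- p
  assign("perm_cache", cache, envir = .statedyn_env)
  p
}

.statedyn_env <- new.env(parent = emptyenv())

# K x K pairwise score matrix between two centroid sets
centroid_score_matrix <- function(C1, C2, mode) {
  C1 <- as.matrix(C1); C2 <- as.matrix(C2)
  if (ncol(C1) != ncol(C2) || nrow(C1) != nrow(C2))
    stop("centroid sets must have identical dimensions")
  if (mode == "cosine") {
    n1 <- sqrt(rowSums(C1^2)); n2 <- sqrt(rowSums(C2^2))
    if (any(n1 == 0) || any(n2 == 0))
      stop("cosine matching undefined for a zero-norm centroid")
    tcrossprod(C1, C2) / outer(n1, n2)
  } else {
    outer(rowSums(C1^2), rowSums(C2^2), "+") - 2 * tcrossprod(C1, C2)
  }
}

new_state_matching <- function(permutation, score, mode, search) {
  structure(list(permutation = as.integer(permutation),
                 mean_similarity = score, mode = mode, search = search),
            class = "state_matching")
}

#' @export
print.state_matching <- function(x, ...) {
  cat(sprintf("<state_matching> %s/%s: %s; %s = %.4g\n",
              x$mode, x$search, paste(x$permutation, collapse = " "),
              if (x$mode == "cosine") "mean similarity" else "mean sq. distance",
              x$mean_similarity))
  invisible(x)
}

#' Optimal state matching by exhaustive permutation search
#'
#' Evaluates all K! bijections between the states of session 1 and session 2
#' and returns the one maximizing the mean cosine similarity of matched
#' centroids (`mode = "cosine"`) or minimizing the mean squared Euclidean
#' distance (`mode = "euclidean"`). Ties return the lexicographically smallest
#' permutation. Feasible for K up to the `cutover` (default 8); beyond that
#' use [match_greedy()].
#'
#' @param C1,C2 K x N centroid matrices for the two sessions.
#' @param mode `"cosine"` or `"euclidean"`.
#' @param cutover Largest K for which exhaustive search is allowed.
#' @return A `state_matching`: `permutation[l]` is the session-2 state matched
#'   to session-1 state l; `mean_similarity` is the achieved mean score.
#' @export
match_exhaustive <- function(C1, C2, mode = c("cosine", "euclidean"),
                             cutover = 8L) {
  mode <- match.arg(mode)
  S <- centroid_score_matrix(C1, C2, mode)
  K <- nrow(S)
  if (K > cutover)
    stop("exhaustive matching disabled for K = ", K, " > ", cutover,
         "; use match_greedy()")
  P <- perms_lex(K)
  lin <- (P - 1L) * K + col(P)  # S[l, P[m, l]] for every permutation m
  scores <- rowSums(matrix(S[as.vector(lin)], nrow(P), K))
  best <- if (mode == "cosine") which.max(scores) else which.min(scores)
  new_state_matching(P[best, ], scores[best] / K, mode, "exhaustive")
}

#' Approximate state matching by greedy search
#'
#' Repeatedly pairs the unmatched (l, l') with the largest cosine similarity
#' (or smallest squared distance in euclidean mode) until all K states are
#' matched. Ties are broken towards the smallest (l, l') in lexicographic
#' order. Used for K above the exhaustive cutover; never beats the exhaustive
#' objective.
#'
#' @inheritParams match_exhaustive
#' @return A `state_matching`.
#' @export
match_greedy <- function(C1, C2, mode = c("cosine", "euclidean")) {
  mode <- match.arg(mode)
  S <- centroid_score_matrix(C1, C2, mode)
  K <- nrow(S)
  work <- S
  blocked <- if (mode == "cosine") -Inf else Inf
  perm <- integer(K)
  total <- 0
  for (step in seq_len(K)) {
    target <- if (mode == "cosine") max(work) else min(work)
    hits <- which(work == target, arr.ind = TRUE)
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    l <- hits[1L, 1L]; lp <- hits[1L, 2L]
    perm[l] <- lp
    total <- total + S[l, lp]
    work[l, ] <- blocked
    work[, lp] <- blocked
  }
  new_state_matching(perm, total / K, mode, "greedy")
}

#' Match two sessions' states (exhaustive below the cutover, greedy above)
#'
#' @inheritParams match_exhaustive
#' @param search `"auto"` (exhaustive for K <= cutover, greedy otherwise),
#'   `"exhaustive"`, or `"greedy"`.
#' @return A `state_matching`.
#' @export
match_states <- function(C1, C2, mode = c("cosine", "euclidean"),
                         search = c("auto", "exhaustive", "greedy"),
                         cutover = 8L) {
  mode <- match.arg(mode)
  search <- match.arg(search)
  K <- nrow(as.matrix(C1))
  if (search == "auto") search <- if (K <= cutover) "exhaustive" else "greedy"
  switch(search,
         exhaustive = match_exhaustive(C1, C2, mode, cutover = cutover),
         greedy = match_greedy(C1, C2, mode))
}

#' Centroid dissimilarity between two matched state sets
#'
#' `1 - (centroid similarity)`, where the centroid similarity is the mean
#' cosine similarity over the K matched centroid pairs. Ranges between 0 and
#' 2: 0 iff every matched pair is exactly parallel, 2 iff every matched pair
#' is antiparallel.
#'
#' @param C1,C2 K x N centroid matrices.
#' @param matching A `state_matching` in cosine mode (from [match_states()]);
#'   computed if omitted.
#' @return A number in \[0, 2\].
#' @export
centroid_dissimilarity <- function(C1, C2, matching = NULL) {
  if (is.null(matching)) matching <- match_states(C1, C2, mode = "cosine")
  if (matching$mode != "cosine")
    stop("centroid dissimilarity is defined for cosine-mode matchings")
  S <- centroid_score_matrix(C1, C2, "cosine")
  K <- nrow(S)
  1 - mean(S[cbind(seq_len(K), matching$permutation)])
}

#' Total variation distance between two matched K-vectors
#'
#' `max_l |Q_i(l) - Q_j(l)|` for observables already aligned by a state
#' matching (coverage, frequency, or lifespan vectors).
#'
#' @param q_i,q_j Numeric vectors of equal length.
#' @return Non-negative number.
#' @export
tv_distance <- function(q_i, q_j) {
  if (length(q_i) != length(q_j)) stop("vectors must have equal length")
  max(abs(q_i - q_j))
}

#' Frobenius distance between two matched transition matrices
#'
#' `sqrt(sum_(l,l') |P_i[l,l'] - P_j[l,l']|^2)` for matrices whose rows and
#' columns have been permuted consistently by a state matching.
#'
#' @param p_i,p_j K x K numeric matrices.
#' @return Non-negative number.
#' @export
frobenius_distance <- function(p_i, p_j) {
  if (!all(dim(p_i) == dim(p_j))) stop("matrices must have equal dimensions")
  sqrt(sum((p_i - p_j)^2))
}

OBSERVABLE_NAMES <- c("centroid", "coverage", "frequency", "lifespan",
                      "transition")

#' All five discrepancies between two sessions under one state matching
#'
#' Determines the state matching once from the centroids (per `mode` and
#' `search`), aligns session j's observables by that matching, and computes
#' the observable-appropriate measure: centroid dissimilarity (cosine mode) or
#' mean squared Euclidean distance (euclidean mode) for the centroids, total
#' variation for coverage/frequency/lifespan, and the Frobenius distance for
#' the transition probability matrix. One matching shared by all observables
#' keeps them comparable.
#'
#' @param obs_i,obs_j [session_observables()] with the same K.
#' @param mode `"cosine"` or `"euclidean"` centroid comparison.
#' @param search Matching search strategy (see [match_states()]).
#' @param cutover Exhaustive/greedy cutover.
#' @return Named list: the five discrepancy `values` and the `matching`.
#' @export
pair_discrepancies <- function(obs_i, obs_j, mode = c("cosine", "euclidean"),
                               search = c("auto", "exhaustive", "greedy"),
                               cutover = 8L) {
  mode <- match.arg(mode)
  search <- match.arg(search)
  if (obs_i$K != obs_j$K) stop("sessions have different K")
  m <- match_states(obs_i$centroids, obs_j$centroids, mode = mode,
                    search = search, cutover = cutover)
  perm <- m$permutation
  S <- centroid_score_matrix(obs_i$centroids, obs_j$centroids, mode)
  K <- obs_i$K
  matched <- S[cbind(seq_len(K), perm)]
  centroid_val <- if (mode == "cosine") 1 - mean(matched) else mean(matched)
  Pj <- obs_j$transition[perm, perm, drop = FALSE]
  values <- c(
    centroid = centroid_val,
    coverage = tv_distance(obs_i$coverage, obs_j$coverage[perm]),
    frequency = tv_distance(obs_i$frequency, obs_j$frequency[perm]),
    lifespan = tv_distance(as.numeric(obs_i$lifespan),
                           as.numeric(obs_j$lifespan)[perm]),
    transition = frobenius_distance(unclass(obs_i$transition), Pj)
  )
  list(values = values, matching = m)
}

#' Discrepancy between two sessions for one observable
#'
#' @inheritParams pair_discrepancies
#' @param observable One of `"centroid"`, `"coverage"`, `"frequency"`,
#'   `"lifespan"`, `"transition"`.
#' @return An object of class `discrepancy`: list with `observable`, `value`,
#'   `matching`.
#' @export
session_discrepancy <- function(obs_i, obs_j,
                                observable = OBSERVABLE_NAMES,
                                mode = c("cosine", "euclidean"),
                                search = c("auto", "exhaustive", "greedy"),
                                cutover = 8L) {
  observable <- match.arg(observable)
  res <- pair_discrepancies(obs_i, obs_j, mode = mode, search = search,
                            cutover = cutover)
  structure(list(observable = observable,
                 value = unname(res$values[[observable]]),
                 matching = res$matching),
            class = "discrepancy")
}

#' @export
print.discrepancy <- function(x, ...) {
  cat(sprintf("<discrepancy> %s = %.6g\n", x$observable, x$value))
  invisible(x)
}
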