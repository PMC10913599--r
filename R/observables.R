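#' Coverage of each state
#'
#' Fraction of volumes spent in each state: count of `labels == l` divided by
#' T. Always sums to 1.
#'
#' @param labels Integer label sequence in 1..K.
#' @param K Number of states.
#' @return Numeric vector of length K.
#' @export
state_coverage <- function(labels, K) {
  tabulate(labels, K) / length(labels)
}

# run-length encoding of the label sequence
label_runs <- function(labels) {
  r <- rle(as.integer(labels))
  list(values = r$values, lengths = r$lengths)
}

#' Frequency of appearance of each state
#'
#' Number of maximal runs (consecutive appearances count once) of each state,
#' divided by T, i.e. appearances per volume.
#'
#' @inheritParams state_coverage
#' @return Numeric vector of length K.
#' @export
state_frequency <- function(labels, K) {
  r <- label_runs(labels)
  tabulate(r$values, K) / length(labels)
}

#' Average lifespan of each state
#'
#' Mean length (in volumes, i.e. TR units) of the maximal runs of each state:
#' total volumes in the state divided by its number of runs. States absent
#' from the sequence get lifespan 0 (flagged via the `absent` attribute), so
#' downstream total-variation comparisons stay well-defined and penalize a
#' state present in one session but not the other. Boundary runs (truncated by
#' the start or end of the session) are included.
#'
#' @inheritParams state_coverage
#' @return Numeric vector of length K with attribute `absent` (logical K).
#' @export
state_lifespan <- function(labels, K) {
  r <- label_runs(labels)
  n_runs <- tabulate(r$values, K)
  tot <- tabulate(labels, K)
  out <- ifelse(n_runs > 0L, tot / pmax(n_runs, 1L), 0)
  attr(out, "absent") <- n_runs == 0L
  out
}

#' Transition probability matrix of the label sequence
#'
#' Counts transitions between *distinct* consecutive states (dwelling in the
#' same state is not a transition; there is no wraparound from the last to the
#' first volume) and row-normalizes: `p[l, l'] = n[l, l'] / sum_{l'' != l}
#' n[l, l'']`, with zero diagonal. A state with no outgoing transitions keeps
#' an all-zero row.
#'
#' @inheritParams state_coverage
#' @return K x K matrix with attribute `counts` (the integer transition
#'   counts n\[l, l'\]).
#' @export
state_transition_matrix <- function(labels, K) {
  labels <- as.integer(labels)
  from <- labels[-length(labels)]
  to <- labels[-1L]
  keep <- from != to
  n <- matrix(0L, K, K)
  if (any(keep)) {
    tab <- table(factor(from[keep], levels = seq_len(K)),
                 factor(to[keep], levels = seq_len(K)))
    n <- matrix(as.integer(tab), K, K)
  }
  rs <- rowSums(n)
  P <- n / ifelse(rs > 0, rs, 1)
  P[rs == 0, ] <- 0
  attr(P, "counts") <- n
  P
}

#' All five state-transition observables for one session
#'
#' Bundles the five observables used for the test-retest comparison: the K
#' centroid vectors, coverage, frequency of appearance, average lifespan, and
#' the transition probability matrix.
#'
#' @param part A [state_partition()], or an integer label sequence if
#'   `centroids` is supplied.
#' @param centroids Optional K x N centroid matrix when `part` is a raw label
#'   vector.
#' @param K Number of states (taken from `part` when it is a partition).
#' @return An object of class `session_observables` with fields `centroids`,
#'   `coverage`, `frequency`, `lifespan`, `transition`, `K`.
#' @export
session_observables <- function(part, centroids = NULL, K = NULL) {
  if (inherits(part, "state_partition")) {
    labels <- part$labels
    centroids <- part$centroids
    K <- part$K
  } else {
    labels <- as.integer(part)
    if (is.null(centroids) || is.null(K))
      stop("supply a state_partition, or labels plus centroids and K")
    centroids <- as.matrix(centroids)
  }
  structure(
    list(centroids = centroids,
         coverage = state_coverage(labels, K),
         frequency = state_frequency(labels, K),
         lifespan = state_lifespan(labels, K),
         transition = state_transition_matrix(labels, K),
         K = K),
    class = "session_observables"
  )
}

#' @export
print.session_observables <- function(x, ...) {
  cat(sprintf("<session_observables> K=%d\n", x$K))
  cat(" coverage: ", paste(signif(x$coverage, 3), collapse = " "), "\n")
  cat(" frequency:", paste(signif(x$frequency, 3), collapse = " "), "\n")
  cat(" lifespan: ", paste(signif(x$lifespan, 3), collapse = " "), "\n")
  invisible(x)
}
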