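## ND statistic (between- vs within-participant mean session dissimilarity)
## and its permutation test over a rectangular participant x session grid.
## Grid cells are indexed participant-major: cell(p, s) = (p - 1) * N_s + s.

#' Session-pair index sets for a rectangular study design
#'
#' Enumerates the cell pairs entering the ND statistic: `within` holds every
#' pair of distinct sessions of the same participant
#' (`N_p * N_s * (N_s - 1) / 2` pairs); `between` holds every pair of distinct
#' participants at the *same session index*
#' (`N_s * N_p * (N_p - 1) / 2` pairs).
#'
#' @param n_participants,n_sessions Design dimensions (both >= 2).
#' @return List with integer two-column matrices `within` and `between` of
#'   cell indices.
#' @export
nd_pair_indices <- function(n_participants, n_sessions) {
  Np <- as.integer(n_participants); Ns <- as.integer(n_sessions)
  if (Np < 2L || Ns < 2L) stop("ND requires N_p >= 2 and N_s >= 2")
  cell <- function(p, s) (p - 1L) * Ns + s
  within <- do.call(rbind, lapply(seq_len(Np), function(p) {
    idx <- utils::combn(Ns, 2L)
    cbind(cell(p, idx[1L, ]), cell(p, idx[2L, ]))
  }))
  between <- do.call(rbind, lapply(seq_len(Ns), function(s) {
    idx <- utils::combn(Np, 2L)
    cbind(cell(idx[1L, ], s), cell(idx[2L, ], s))
  }))
  list(within = within, between = between)
}

#' Precompute all pairwise session discrepancies
#'
#' Builds the symmetric M x M matrix of discrepancies between every pair of
#' grid cells (M = N_p * N_s). The permutation test only re-indexes this cache
#' (shuffling permutes cell identities, so every replicate's pairs are already
#' in it), which makes 10^4 replicates cheap.
#'
#' @param payloads List of M observable payloads in participant-major cell
#'   order.
#' @param pair_fn Function of two payloads returning their dissimilarity
#'   (symmetric, >= 0).
#' @return M x M numeric matrix with zero diagonal.
#' @export
discrepancy_cache <- function(payloads, pair_fn) {
  M <- length(payloads)
  D <- matrix(0, M, M)
  for (i in seq_len(M - 1L)) {
    for (j in seq.int(i + 1L, M)) {
      D[i, j] <- D[j, i] <- pair_fn(payloads[[i]], payloads[[j]])
    }
  }
  D
}

# ND from a cache under a cell relabeling `perm` (perm[pos] = payload at pos)
nd_from_cache <- function(D, pairs, perm = NULL) {
  w <- pairs$within; b <- pairs$between
  if (!is.null(perm)) {
    w <- cbind(perm[w[, 1L]], perm[w[, 2L]])
    b <- cbind(perm[b[, 1L]], perm[b[, 2L]])
  }
  den <- mean(D[w])
  if (den == 0) return(NA_real_)  # degenerate: identical within-participant
  mean(D[b]) / den
}

#' Normalized distance (ND) between- vs within-participant dissimilarity
#'
#' `ND(q)` is the mean dissimilarity between sessions of *different*
#' participants at the same session index, divided by the mean dissimilarity
#' between sessions of the *same* participant. ND > 1 indicates that the
#' observable is more consistent within than between participants
#' (fingerprinting potential).
#'
#' @param payloads List of `N_p * N_s` observable payloads in
#'   participant-major cell order, or a precomputed M x M discrepancy matrix
#'   from [discrepancy_cache()].
#' @param n_participants,n_sessions Design dimensions.
#' @param discrepancy Pairwise dissimilarity function (required when
#'   `payloads` is a list).
#' @return The ND value (> 0).
#' @export
compute_nd <- function(payloads, n_participants, n_sessions,
                       discrepancy = NULL) {
  D <- as_cache(payloads, n_participants, n_sessions, discrepancy)
  pairs <- nd_pair_indices(n_participants, n_sessions)
  nd <- nd_from_cache(D, pairs)
  if (is.na(nd))
    stop("degenerate ND: all within-participant session pairs have zero ",
         "dissimilarity")
  nd
}

as_cache <- function(payloads, n_participants, n_sessions, discrepancy) {
  if (is.matrix(payloads)) {
    D <- payloads
  } else {
    if (is.null(discrepancy))
      stop("supply a discrepancy function, or a precomputed cache matrix")
    D <- discrepancy_cache(payloads, discrepancy)
  }
  M <- n_participants * n_sessions
  if (!all(dim(D) == c(M, M)))
    stop("cache must be ", M, " x ", M, " for this design")
  D
}

#' Permutation test for the ND statistic
#'
#' Null hypothesis: the observable payloads are exchangeable across all
#' participant-session cells. Each of the R replicates applies an independent
#' uniform random permutation to the `N_p * N_s` cells and recomputes ND. The
#' one-sided p-value (default) is the fraction of replicates whose ND is `>=`
#' the empirical ND (ties count as exceedances); `two_sided = TRUE` instead
#' counts replicates with `|ND' - 1| >= |ND - 1|`. Replicates with a zero
#' within-participant denominator are counted as exceedances and reported in
#' `n_degenerate`.
#'
#' @inheritParams compute_nd
#' @param R Number of permutation replicates (default 10^4).
#' @param seed Integer seed for the permutations.
#' @param two_sided Use the `|ND - 1|` exceedance rule instead of the
#'   one-sided "larger ND" rule.
#' @return An object of class `nd_result`: `nd`, `null_sample` (length R),
#'   `p_value`, `p_lt_1_over_R` flag, `R`, `seed`, `n_degenerate`,
#'   `two_sided`.
#' @export
permutation_test <- function(payloads, n_participants, n_sessions,
                             discrepancy = NULL, R = 10000L, seed = 1L,
                             two_sided = FALSE) {
  D <- as_cache(payloads, n_participants, n_sessions, discrepancy)
  pairs <- nd_pair_indices(n_participants, n_sessions)
  nd_obs <- nd_from_cache(D, pairs)
  if (is.na(nd_obs))
    stop("degenerate ND: all within-participant session pairs have zero ",
         "dissimilarity")
  M <- n_participants * n_sessions
  if (!is.null(seed)) set.seed(as.integer(seed))
  R <- as.integer(R)
  perms <- matrix(0L, R, M)
  for (r in seq_len(R)) perms[r, ] <- sample.int(M)
  w <- pairs$within; b <- pairs$between
  num <- pair_means_under_perms(D, perms, b)
  den <- pair_means_under_perms(D, perms, w)
  null_sample <- ifelse(den == 0, NA_real_, num / den)
  n_degenerate <- sum(is.na(null_sample))
  exceed <- if (two_sided) {
    is.na(null_sample) | abs(null_sample - 1) >= abs(nd_obs - 1)
  } else {
    is.na(null_sample) | null_sample >= nd_obs
  }
  k <- sum(exceed)
  structure(
    list(nd = nd_obs, null_sample = null_sample, p_value = k / R,
         p_lt_1_over_R = (k == 0L), R = R, seed = seed,
         n_degenerate = n_degenerate, two_sided = two_sided),
    class = "nd_result"
  )
}

# rowMeans of D over a pair set, for every permutation row at once
pair_means_under_perms <- function(D, perms, pairs) {
  a <- perms[, pairs[, 1L], drop = FALSE]
  b <- perms[, pairs[, 2L], drop = FALSE]
  vals <- matrix(D[cbind(as.vector(a), as.vector(b))], nrow(perms))
  rowMeans(vals)
}

#' Format a permutation p-value the way it is reported
#'
#' Zero exceedances are reported as `"< 1/R"` (e.g. `"< 1e-04"` for
#' R = 10^4) rather than 0, since the resolution of the test is 1/R.
#'
#' @param p Numeric p-value (k / R).
#' @param R Number of replicates.
#' @return Character scalar.
#' @export
format_p_value <- function(p, R) {
  if (p == 0) paste0("< ", format(1 / R, scientific = TRUE)) else format(p)
}

#' @export
print.nd_result <- function(x, ...) {
  cat(sprintf("<nd_result> ND = %.4f, p %s (R = %d%s)\n",
              x$nd,
              if (x$p_lt_1_over_R) format_p_value(0, x$R)
              else paste("=", format(x$p_value)),
              x$R,
              if (x$two_sided) ", two-sided" else ""))
  if (x$n_degenerate > 0L)
    cat(" note:", x$n_degenerate, "degenerate replicates counted as exceedances\n")
  invisible(x)
}

#' Bonferroni-equivalent uncorrected threshold
#'
#' @param n_comparisons Number of simultaneous tests.
#' @param alpha Family-wise level (default 0.05).
#' @return `alpha / n_comparisons`.
#' @export
bonferroni_threshold <- function(n_comparisons, alpha = 0.05) {
  alpha / n_comparisons
}

#' Run the full reliability study
#'
#' For every (method, K) pair: clusters every session of the study, computes
#' the five state-transition observables, builds the pairwise discrepancy
#' caches (one state matching per session pair, shared across observables),
#' and runs the ND permutation test per observable. Results are annotated for
#' significance at 0.05, 0.001, and the Bonferroni-corrected 0.05 level
#' (0.05 / number of comparisons; 135 for the full 3-method x 9-K x
#' 5-observable grid).
#'
#' @param sessions Either a `study_manifest` (files are loaded from disk) or a
#'   list of [roi_time_series()] in participant-major cell order.
#' @param manifest Required when `sessions` is a list: the `study_manifest`
#'   giving the design dimensions (or a list with `n_participants`,
#'   `n_sessions`).
#' @param treatment Global-signal treatment applied to each session (see
#'   [apply_treatment()]). Default `"none"`: synthetic studies from
#'   [generate_study()] already satisfy the treatment-2 convention
#'   (mean-0 / SD-1 rows). Pass `"2"` plus `map` for raw ROI data.
#' @param map Optional [symmetry_map()] for treatments 1 and 2.
#' @param methods Clustering methods to compare.
#' @param Ks Integer vector of state counts.
#' @param observables Subset of the five observable names.
#' @param mode,search Centroid matching configuration (see [match_states()]).
#' @param R Permutation replicates per cell.
#' @param seed Study-level seed; per-(session, method, K) clustering seeds and
#'   per-cell permutation seeds are derived from it deterministically.
#' @param n_comparisons Bonferroni denominator; defaults to the number of
#'   result rows produced.
#' @param two_sided Sidedness of the permutation test.
#' @return data.frame with columns `method, K, observable, nd, p_value,
#'   sig_05, sig_001, sig_bonf`; the full `nd_result` objects are attached as
#'   `attr(, "nd_results")` and the Bonferroni threshold as
#'   `attr(, "bonferroni")`.
#' @export
run_study <- function(sessions, manifest = NULL,
                      treatment = "none", map = NULL,
                      methods = c("kmeans", "taahc", "bisecting_kmeans"),
                      Ks = 2:10,
                      observables = OBSERVABLE_NAMES,
                      mode = c("cosine", "euclidean"),
                      search = c("auto", "exhaustive", "greedy"),
                      R = 10000L, seed = 1L, n_comparisons = NULL,
                      two_sided = FALSE) {
  mode <- match.arg(mode)
  search <- match.arg(search)
  observables <- match.arg(observables, OBSERVABLE_NAMES, several.ok = TRUE)
  if (inherits(sessions, "study_manifest")) {
    manifest <- sessions
    sessions <- lapply(seq_len(nrow(manifest$entries)), function(i) {
      e <- manifest$entries[i, ]
      load_session(e$file, e$participant, e$session)
    })
  }
  if (is.null(manifest))
    stop("a manifest (or design dimensions) is required with a session list")
  Np <- manifest$n_participants; Ns <- manifest$n_sessions
  if (length(sessions) != Np * Ns)
    stop("expected ", Np * Ns, " sessions, got ", length(sessions))
  mats <- lapply(sessions, function(s) {
    X <- if (inherits(s, "roi_time_series")) s$data else as.matrix(s)
    if (treatment == "none") X
    else apply_treatment(X, treatment, map = map,
                         pre_stage_cols = seq_len(ncol(X)))
  })

  # deterministic seed streams derived from the study seed
  set.seed(as.integer(seed))
  n_cells <- length(methods) * length(Ks)
  clust_seeds <- matrix(sample.int(.Machine$integer.max,
                                   n_cells * length(mats)),
                        nrow = n_cells)
  perm_seeds <- sample.int(.Machine$integer.max, n_cells)

  rows <- list()
  nd_results <- list()
  cell <- 0L
  for (method in methods) {
    for (K in Ks) {
      cell <- cell + 1L
      obs <- vector("list", length(mats))
      for (i in seq_along(mats)) {
        part <- estimate_states(mats[[i]], K, method = method,
                                seed = clust_seeds[cell, i])
        obs[[i]] <- session_observables(part)
      }
      caches <- observable_caches(obs, mode = mode, search = search)
      for (ob in observables) {
        key <- paste(method, K, ob, sep = "|")
        # a cell can be intrinsically degenerate: e.g. at K = 2 every
        # session's zero-diagonal transition matrix is [[0,1],[1,0]], so all
        # pairwise Frobenius distances vanish and ND is 0/0; record NA
        res <- tryCatch(
          permutation_test(caches[[ob]], Np, Ns, R = R,
                           seed = perm_seeds[cell], two_sided = two_sided),
          error = function(e) {
            if (grepl("degenerate ND", conditionMessage(e))) NULL else stop(e)
          })
        if (is.null(res)) {
          warning("degenerate ND for (", method, ", K=", K, ", ", ob,
                  "): all within-participant dissimilarities are zero; ",
                  "cell recorded as NA", call. = FALSE)
          rows[[key]] <- data.frame(method = method, K = K, observable = ob,
                                    nd = NA_real_, p_value = NA_real_,
                                    stringsAsFactors = FALSE)
        } else {
          nd_results[[key]] <- res
          rows[[key]] <- data.frame(method = method, K = K, observable = ob,
                                    nd = res$nd, p_value = res$p_value,
                                    stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (is.null(n_comparisons)) n_comparisons <- nrow(out)
  thr <- bonferroni_threshold(n_comparisons)
  out$sig_05 <- out$p_value < 0.05
  out$sig_001 <- out$p_value < 0.001
  out$sig_bonf <- out$p_value < thr
  attr(out, "nd_results") <- nd_results
  attr(out, "bonferroni") <- thr
  out
}

#' Discrepancy caches for all five observables of a study
#'
#' Computes, for every pair of grid cells, the state matching once (from
#' centroids) and all five discrepancy values under it, returning one M x M
#' cache matrix per observable.
#'
#' @param obs_list List of [session_observables()] in cell order.
#' @inheritParams pair_discrepancies
#' @return Named list of five M x M matrices.
#' @export
observable_caches <- function(obs_list, mode = c("cosine", "euclidean"),
                              search = c("auto", "exhaustive", "greedy"),
                              cutover = 8L) {
  mode <- match.arg(mode)
  search <- match.arg(search)
  M <- length(obs_list)
  caches <- lapply(OBSERVABLE_NAMES, function(nm) matrix(0, M, M))
  names(caches) <- OBSERVABLE_NAMES
  for (i in seq_len(M - 1L)) {
    for (j in seq.int(i + 1L, M)) {
      vals <- pair_discrepancies(obs_list[[i]], obs_list[[j]], mode = mode,
                                 search = search, cutover = cutover)$values
      for (nm in OBSERVABLE_NAMES) {
        caches[[nm]][i, j] <- caches[[nm]][j, i] <- vals[[nm]]
      }
    }
  }
  caches
}
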