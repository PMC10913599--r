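## Synthetic multi-participant, multi-session studies with latent discrete
## state dynamics: participant-specific centroid rotations and transition
## matrices, Markov state sequences, Gaussian emissions, and the row
## standardization that the pipeline's default preprocessing would produce.

#' Specification of a synthetic study
#'
#' Defaults describe a realistic resting-state study at the scale of the data
#' this pipeline targets: 8 participants x 10 sessions of 818 volumes over 8
#' ROIs, K = 4 latent states, self-transition probability 0.7 (geometric mean
#' dwell time 1/(1 - 0.7) = 3.3 volumes, the observed scale at K = 4), and
#' emission noise `noise_sd = 0.25` per coordinate around unit-norm centroids
#' (chosen so the squared cosine between a volume and its centroid is about
#' 0.7, matching the ~70% explained variance seen at K = 4).
#'
#' @param n_participants,n_sessions,t_volumes,n_rois,k_states Design sizes.
#' @param dwell_prob Self-transition probability per volume, in \[0, 1).
#' @param participant_divergence Rotation angle (radians, default 0.5 ~ 29
#'   degrees) applied to the base centroids per participant, within the span
#'   of the base centroids; 0 means all participants share centroids.
#' @param noise_sd Emission noise SD per ROI coordinate (> 0).
#' @param transition_jitter Scale of the participant-specific lognormal
#'   perturbation of the off-diagonal transition probabilities; 0 means all
#'   participants share dynamics.
#' @param seed Integer seed for all generator randomness.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_participants = 8L, n_sessions = 10L,
                           t_volumes = 818L, n_rois = 8L, k_states = 4L,
                           dwell_prob = 0.7, participant_divergence = 0.5,
                           noise_sd = 0.25, transition_jitter = 0.3,
                           seed = 1L) {
  stopifnot(n_participants >= 1L, n_sessions >= 1L, t_volumes >= 2L,
            n_rois >= 2L, k_states >= 2L)
  if (dwell_prob < 0 || dwell_prob >= 1) stop("dwell_prob must be in [0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (participant_divergence < 0 || transition_jitter < 0)
    stop("divergence and jitter must be >= 0")
  if (k_states > n_rois)
    warning("k_states > n_rois: centroid directions cannot be near-orthogonal")
  structure(list(n_participants = as.integer(n_participants),
                 n_sessions = as.integer(n_sessions),
                 t_volumes = as.integer(t_volumes),
                 n_rois = as.integer(n_rois),
                 k_states = as.integer(k_states),
                 dwell_prob = dwell_prob,
                 participant_divergence = participant_divergence,
                 noise_sd = noise_sd,
                 transition_jitter = transition_jitter,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# K unit vectors in N dims with pairwise angle >= floor (rejection sampling)
draw_base_centroids <- function(K, N, angle_floor = pi / 4,
                                max_tries = 1000L) {
  cos_max <- cos(angle_floor)
  for (i in seq_len(max_tries)) {
    C <- matrix(stats::rnorm(K * N), K, N)
    C <- C / sqrt(rowSums(C^2))
    G <- tcrossprod(C)
    if (max(abs(G[upper.tri(G)])) <= cos_max) return(C)
  }
  stop("could not draw ", K, " centroid directions in ", N,
       " dimensions with pairwise angle >= ", signif(angle_floor, 3),
       " rad; lower the angle floor or raise n_rois")
}

# rotation by `angle` radians: expm(angle * S) with S a random skew-symmetric
# generator normalized to the scale of a single plane rotation (Frobenius norm
# sqrt(2)). When `basis` (N x k orthonormal) is given, S acts only within that
# subspace, so vectors lying in it are genuinely rotated by about `angle`; a
# generator drawn in the full space could have its rotation planes nearly
# orthogonal to the centroid span, leaving the centroids almost unmoved.
random_rotation <- function(N, angle, basis = NULL) {
  if (angle == 0) return(diag(N))
  k <- if (is.null(basis)) N else ncol(basis)
  A <- matrix(stats::rnorm(k * k), k, k)
  Sk <- (A - t(A)) / 2
  Sk <- Sk * sqrt(2) / sqrt(sum(Sk^2))
  S <- if (is.null(basis)) Sk else basis %*% Sk %*% t(basis)
  as.matrix(Matrix::expm(angle * S))
}

# base transition matrix: diagonal dwell, uniform off-diagonal
base_transition <- function(K, dwell) {
  P <- matrix((1 - dwell) / (K - 1), K, K)
  diag(P) <- dwell
  P
}

# participant perturbation: lognormal jitter on the off-diagonals, rows
# renormalized so off-diagonals still sum to 1 - dwell
jitter_transition <- function(P, jitter) {
  K <- nrow(P)
  if (jitter == 0) return(P)
  dwell <- diag(P)
  off <- P * exp(matrix(stats::rnorm(K * K, sd = jitter), K, K))
  diag(off) <- 0
  off <- off / rowSums(off) * (1 - dwell)
  diag(off) <- dwell
  off
}

# zero-diagonal, row-normalized version: the recovery target for the
# transition-probability observable (which excludes self-transitions)
off_diagonal_normalized <- function(P) {
  Q <- P
  diag(Q) <- 0
  rs <- rowSums(Q)
  Q <- Q / ifelse(rs > 0, rs, 1)
  Q[rs == 0, ] <- 0
  Q
}

simulate_chain <- function(P, T_) {
  K <- nrow(P)
  lab <- integer(T_)
  lab[1L] <- sample.int(K, 1L)
  for (t in seq_len(T_ - 1L)) {
    lab[t + 1L] <- sample.int(K, 1L, prob = P[lab[t], ])
  }
  lab
}

#' Generate a synthetic multi-participant, multi-session study
#'
#' Draws K base centroid directions (unit vectors with pairwise angle at least
#' `angle_floor`); per participant, rotates all base centroids by a random
#' rotation of magnitude `participant_divergence` and perturbs a shared
#' transition matrix (diagonal = `dwell_prob`, uniform off-diagonals) by
#' `transition_jitter`; per session, simulates the participant's Markov chain
#' for `t_volumes` steps and emits `x_t = c(state_t) + N(0, noise_sd^2)`;
#' finally standardizes every row to mean 0 / population SD 1 (the convention
#' a treatment-2 pipeline would establish, so sigma_t = 1 downstream).
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional directory; when given, per-session CSVs and a
#'   `manifest.csv` are written there via the I/O layer.
#' @param angle_floor Minimum pairwise angle between base centroid directions.
#' @return List with `manifest` (a `study_manifest`), `sessions` (list of
#'   [roi_time_series()] in participant-major cell order), `truth` (base and
#'   per-participant centroids, per-participant full and zero-diagonal
#'   transition matrices, and per-session label sequences), and `spec`.
#' @export
generate_study <- function(spec, dir = NULL, angle_floor = pi / 4) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  K <- spec$k_states; N <- spec$n_rois; T_ <- spec$t_volumes
  Np <- spec$n_participants; Ns <- spec$n_sessions

  base_c <- draw_base_centroids(K, N, angle_floor)
  span_basis <- qr.Q(qr(t(base_c)))[, seq_len(min(K, N)), drop = FALSE]
  P0 <- base_transition(K, spec$dwell_prob)

  centroids <- vector("list", Np)
  transitions <- vector("list", Np)
  labels <- vector("list", Np)
  sessions <- vector("list", Np * Ns)
  entries <- data.frame(participant = character(0), session = character(0),
                        file = character(0), stringsAsFactors = FALSE)
  for (p in seq_len(Np)) {
    Rp <- random_rotation(N, spec$participant_divergence, span_basis)
    centroids[[p]] <- base_c %*% t(Rp)
    transitions[[p]] <- jitter_transition(P0, spec$transition_jitter)
    labels[[p]] <- vector("list", Ns)
    pid <- sprintf("sub%02d", p)
    for (s in seq_len(Ns)) {
      sid <- sprintf("ses%02d", s)
      lab <- simulate_chain(transitions[[p]], T_)
      X <- centroids[[p]][lab, , drop = FALSE] +
        matrix(stats::rnorm(T_ * N, sd = spec$noise_sd), T_, N)
      X <- standardize_rows(X)
      labels[[p]][[s]] <- lab
      cellidx <- (p - 1L) * Ns + s
      path <- if (is.null(dir)) NA_character_
              else file.path(dir, sprintf("%s_%s.csv", pid, sid))
      sessions[[cellidx]] <- roi_time_series(X, pid, sid)
      entries <- rbind(entries, data.frame(participant = pid, session = sid,
                                           file = path,
                                           stringsAsFactors = FALSE))
    }
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_along(sessions)) {
      utils::write.table(sessions[[i]]$data, entries$file[i], sep = ",",
                         row.names = FALSE, col.names = FALSE)
    }
    utils::write.csv(entries, file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(manifest = study_manifest(entries),
       sessions = sessions,
       truth = list(base_centroids = base_c,
                    # recovery target: the emitted volumes are standardized
                    # per row, so a state's noiseless image is the
                    # standardized centroid, not the raw rotated vector
                    centroids = lapply(centroids, standardize_rows),
                    centroids_raw = centroids,
                    transition_full = transitions,
                    transition = lapply(transitions, off_diagonal_normalized),
                    labels = labels),
       spec = spec)
}

standardize_rows <- function(X) {
  mu <- rowMeans(X)
  Xc <- X - mu
  sd_t <- sqrt(rowMeans(Xc^2))
  if (any(sd_t == 0)) stop("degenerate emitted volume (zero spatial variance)")
  Xc / sd_t
}

#' Parameter-recovery report against the generator's ground truth
#'
#' Clusters every session of a synthetic study with the requested method and
#' K, matches the estimated states to the participant's true centroids
#' (exhaustive cosine matching), and reports per session: the mean matched
#' cosine similarity to the true centroids, label accuracy after matching, the
#' total-variation distances of coverage/frequency/lifespan against the
#' observables of the true label sequence, and the Frobenius distances of the
#' estimated transition matrix against both the true-label transition matrix
#' and the generator's zero-diagonal transition matrix.
#'
#' @param study Output of [generate_study()].
#' @param method Clustering method (see [estimate_states()]).
#' @param K Number of states; defaults to the generator's `k_states`.
#' @param seed Seed for the per-session clustering (one stream, derived).
#' @return data.frame with one row per session.
#' @export
recover_parameters <- function(study, method = "kmeans", K = NULL, seed = 1L) {
  spec <- study$spec
  if (is.null(K)) K <- spec$k_states
  if (K != spec$k_states)
    stop("recovery requires K equal to the generator's k_states (",
         spec$k_states, ")")
  Np <- spec$n_participants; Ns <- spec$n_sessions
  set.seed(as.integer(seed))
  sess_seeds <- sample.int(.Machine$integer.max, Np * Ns)
  rows <- vector("list", Np * Ns)
  for (p in seq_len(Np)) {
    true_c <- study$truth$centroids[[p]]
    for (s in seq_len(Ns)) {
      i <- (p - 1L) * Ns + s
      X <- study$sessions[[i]]$data
      part <- estimate_states(X, K, method = method, seed = sess_seeds[i])
      m <- match_exhaustive(part$centroids, true_c, mode = "cosine")
      true_lab <- study$truth$labels[[p]][[s]]
      acc <- mean(m$permutation[part$labels] == true_lab)
      est_obs <- session_observables(part)
      true_obs <- session_observables(true_lab, centroids = true_c, K = K)
      perm <- m$permutation
      tvs <- c(
        coverage = tv_distance(est_obs$coverage, true_obs$coverage[perm]),
        frequency = tv_distance(est_obs$frequency, true_obs$frequency[perm]),
        lifespan = tv_distance(as.numeric(est_obs$lifespan),
                               as.numeric(true_obs$lifespan)[perm])
      )
      fro_lab <- frobenius_distance(unclass(est_obs$transition),
                                    unclass(true_obs$transition)[perm, perm])
      fro_gen <- frobenius_distance(unclass(est_obs$transition),
                                    study$truth$transition[[p]][perm, perm])
      rows[[i]] <- data.frame(
        participant = study$sessions[[i]]$participant_id,
        session = study$sessions[[i]]$session_id,
        centroid_cosine = m$mean_similarity,
        label_accuracy = acc,
        tv_coverage = tvs[["coverage"]],
        tv_frequency = tvs[["frequency"]],
        tv_lifespan = tvs[["lifespan"]],
        frobenius_transition = fro_lab,
        frobenius_generator = fro_gen,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
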