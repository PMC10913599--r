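---
title: "Discrete brain-state dynamics and their test-retest reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete brain-state dynamics and their test-retest reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statedyn)
```

## The problem

Resting-state fMRI activity can be summarized as a sequence of discrete
spatial patterns ("states"), in the spirit of EEG/MEG microstate analysis:
each acquired volume `x_t` (a vector of N ROI signals) is assigned to one of
K clusters, and the session is then described by the cluster centroids plus
the statistics of the label sequence. `statedyn` implements that pipeline
end to end and asks the follow-up question that matters for individual
fingerprinting: *are these state-transition summaries more similar between
two sessions of the same person than between sessions of different people?*

The package covers:

1. **Preprocessing** — global signal removal and symmetric-ROI aggregation
   (`remove_global_signal()`, `aggregate_symmetric()`, `apply_treatment()`).
2. **State estimation** — seven clustering methods (`estimate_states()`),
   scored by total global explained variance (`gev_total()`) and
   within-cluster sum of squares (`wcss()`).
3. **Observables** — coverage, frequency of appearance, average lifespan,
   and the transition probability matrix per session
   (`session_observables()`).
4. **Cross-session matching** — optimal (exhaustive) or greedy bijections
   between two sessions' state sets and per-observable discrepancy measures
   (`match_states()`, `pair_discrepancies()`).
5. **Reliability** — the normalized distance ND and its permutation test
   over a rectangular participant-by-session study (`compute_nd()`,
   `permutation_test()`, `run_study()`).
6. **Synthetic studies** — a generative model with latent Markov state
   dynamics for validating every stage without any data download
   (`synthetic_spec()`, `generate_study()`, `recover_parameters()`).

## Model and statistics

### Global signal removal

For each volume the across-ROI mean is subtracted and the result divided by
the across-ROI *population* standard deviation (divisor N, not N − 1; the
definition is explicit about this). After this step every row has mean 0
and spatial SD 1, so the global field power `sigma_t` is identically 1
downstream. Three composite treatments are supported: treatment 1 =
GSR then symmetric-pair aggregation; treatment 2 = treatment 1 plus a final
GSR over the aggregated ROIs (the default — it yields the best clustering
quality and guarantees `sigma_t = 1`); treatment 3 = GSR only, no
aggregation. A wider first-stage GSR over a superset of ROIs is applied when
the caller supplies the superset (`pre_stage_cols`); otherwise it is skipped
with a message, because columns that were discarded upstream cannot be
replayed.

Volumes that are constant across ROIs (`sigma_t = 0`) abort with an error
naming the offending volume: real BOLD data never does this, so silence
would only hide a misuse.

### State estimation

All seven methods share the contract: labels `1..K` (every state non-empty),
K centroid rows, deterministic output given `(X, K, method, seed)`, states
relabeled by first appearance in time.

* **K-means**: k-means++ seeding, Lloyd iterations until the absolute change
  in the residual sum of squares falls below `1e-5` (cap 300 iterations,
  error past the cap). Ten independent restarts are run and the lowest final
  RSS wins — matching the convention of the reference implementation the
  original pipeline used; a single restart occasionally lands in a visibly
  bad local optimum, which would inflate within-participant dissimilarity.
  Empty clusters are re-seeded with the point farthest from its centroid
  (standard remedy; keeps K fixed).
* **K-medoids**: k-means++-style seeding on data points; each medoid is the
  member minimizing total Euclidean distance to the rest of its cluster; the
  iteration stops when the medoid set repeats (this also terminates
  oscillations, which the plain "stops changing" rule would not).
* **Ward**: standard minimum-variance agglomeration (`hclust`/`ward.D2`),
  cut at K.
* **AAHC / TAAHC**: start from T singleton clusters; repeatedly *atomize*
  the worst cluster — smallest GEV contribution for AAHC, smallest summed
  cosine similarity (CRS) for TAAHC — and reassign each freed volume to the
  surviving cluster with the highest cosine similarity; exactly `T - K`
  atomization steps. Ties in the worst-cluster criterion go to the smallest
  cluster index (with singleton starts, early ties are common, so the
  tie-break is part of the contract). The GEV weighting uses `sigma_t^2`
  recomputed from the matrix being clustered, with the denominator summed
  over all volumes.
* **Bisecting K-means**: repeatedly split (by 2-means) the cluster with the
  largest within-cluster sum of squared errors.
* **GMM**: full-covariance Gaussian mixture by EM, `1e-6` ridge on each
  covariance diagonal, initialized from a K-means solution; hard labels by
  maximum posterior component density; centroids are the component means.
  The log-likelihood trace is retained and is non-decreasing.

### Observables and their comparison

Coverage (fraction of volumes per state), frequency (maximal runs per
volume), lifespan (mean run length in TR units; boundary-truncated runs are
included), and the transition matrix (counts of *distinct*-state consecutive
pairs, row-normalized, zero diagonal, no wraparound). A state absent from a
session keeps lifespan 0 with an `absent` flag: 0 keeps the total-variation
comparison well defined and penalizes the mismatch.

To compare two sessions, the K states are matched **once**, from the
centroids, and that single bijection is reused for all five observables
(observable-specific matchings would break cross-observable comparability).
Matching is exhaustive over all K! permutations for K ≤ 8 and greedy above
(configurable cutover), maximizing mean cosine similarity, or minimizing the
mean squared Euclidean distance in the alternative mode, which threads
through to every downstream value. Tie-breaks are lexicographic and
documented. The measures: centroid dissimilarity `1 - mean matched cosine`
(range [0, 2]); total variation `max_l |Q_i(l) - Q_j(l)|` for
coverage/frequency/lifespan; Frobenius distance for transition matrices.
In euclidean mode the centroid value is the mean of `||c - c'||^2` itself
(no square root before averaging — that is how the distance is defined).

### The ND statistic and its permutation test

For a rectangular design (N_p participants × N_s sessions — rectangularity
is enforced at manifest load), with `d~(q(p,s), q(p',s'))` the pairwise
discrepancy of an observable:

* numerator: mean `d~` over all between-participant pairs *at the same
  session index* — `N_s · N_p (N_p − 1) / 2` pairs;
* denominator: mean `d~` over all within-participant session pairs —
  `N_p · N_s (N_s − 1) / 2` pairs.

ND > 1 means the observable is more reproducible within than between
participants. The same-session-index restriction in the numerator is part
of the definition; an all-pairs variant would change the statistic and is
deliberately not used for any reported number.

The permutation test shuffles the `N_p · N_s` observable payloads uniformly
across all cells, recomputes ND each time (R = 10^4 by default), and reports
the fraction of replicates with `ND' >= ND` (the operational one-sided rule;
a `two_sided = TRUE` flag implements `|ND' - 1| >= |ND - 1|` instead). Ties
count as exceedances (conservative). Zero exceedances are reported as
`p < 1/R`, never as 0, since 1/R is the resolution of the test. All
`M(M-1)/2` pairwise discrepancies are computed once and cached; a shuffle
only re-indexes the cache, which is what makes 10^4 replicates cheap — a
permutation relabels which cell holds which payload, so every pair any
replicate needs is already in the cache, and state matching never has to be
re-run.

Replicates with a zero denominator are counted as exceedances and reported
in `n_degenerate`. A *cell* whose observed denominator is zero is recorded
as NA by `run_study()` with a warning rather than aborting the grid. One
such case is structural: at K = 2 the zero-diagonal row-normalized
transition matrix of any session in which both states have an outgoing
transition is `[[0,1],[1,0]]`, so all pairwise Frobenius distances vanish
and ND is 0/0. This is a genuine property of the zero-diagonal convention,
not a numerical accident, and it is surfaced rather than patched.

Significance is annotated at 0.05, 0.001, and Bonferroni-corrected 0.05;
the Bonferroni denominator defaults to the number of result rows actually
produced (135 for the full 3-method × K∈{2..10} × 5-observable grid, where
0.05/135 ≈ 0.00037).

## The synthetic-data generator: what it emulates, and what it does not

`generate_study()` produces the stated world the tests run in:

* K base centroid directions — unit vectors with pairwise angle ≥ 45°
  (rejection sampling; an infeasible floor for the requested K and N is an
  error).
* Per participant, one random rotation of magnitude
  `participant_divergence` applied to all base centroids. The rotation
  generator is drawn *within the span of the base centroids* and normalized
  to the scale of a single plane rotation: a generator drawn in the full
  N-dimensional space can have its rotation planes nearly orthogonal to the
  centroid span, leaving some participants with essentially identical
  centroids — an artifact, not a model feature.
* Per participant, a transition matrix with diagonal `dwell_prob` and
  lognormally jittered off-diagonals renormalized to keep row sums 1. The
  zero-diagonal row-normalized version is recorded as the recovery target,
  matching the pipeline's `p_ll = 0` convention.
* Per session, a Markov chain of length T with Gaussian emissions
  `x_t = c(state) + N(0, noise_sd^2 I)`, then per-row standardization —
  the treatment-2 convention, so `sigma_t = 1` holds downstream exactly.
  Consequently the recovery target for a state's centroid is the
  *standardized* centroid (its noiseless image in the emitted space), and
  `run_study()` defaults to `treatment = "none"` for generated data: the
  rows already satisfy the convention, and re-applying GSR would be a no-op
  on them while treatments 1–2 would additionally demand a meaningless
  symmetry map.

Default parameters and why:

| parameter | default | rationale |
|---|---|---|
| `n_participants`, `n_sessions` | 8, 10 | the target study design |
| `t_volumes` | 818 | one 30-min session at TR = 2.2 s |
| `n_rois` | 8 | symmetrized default-mode network |
| `k_states` | 4 | the headline model order |
| `dwell_prob` | 0.7 | geometric mean lifespan 1/(1−0.7) ≈ 3.3 volumes, the observed scale at K = 4 |
| `noise_sd` | 0.25 | per-coordinate noise around unit centroids giving squared volume-to-centroid cosine ≈ 1/(1+8·0.25²) ≈ 0.7, i.e. ~70% explained variance at K = 4 |
| `participant_divergence` | 0.5 rad | between-participant matched-centroid cosine ≈ 0.88 versus ≈ 0.97–0.99 within: between-participant differences dominate estimation noise, as observed in real test-retest data where centroid position separates individuals most clearly |
| `transition_jitter` | 0.3 | visibly participant-specific stationary distributions and transition profiles without leaving the dwell regime |

What the generator deliberately does **not** emulate: hemodynamic
convolution, temporal autocorrelation of the noise, motion artifacts,
scanner drift, or atlas/parcellation effects. A green test therefore
establishes that the pipeline recovers the statistics of *this* latent-state
world, not that it would denoise real BOLD data; conversely, failures on
real data would implicate the signal model, not the estimator contracts
tested here.

One structural consequence worth knowing: because the diagonal of every
participant's transition matrix is the shared `dwell_prob`, each state's
lifespan distribution is the same geometric law for every participant. The
lifespan observable therefore carries no participant-specific signal in this
world, and its ND hovers around 1 — the generator cannot (and should not)
be used to demonstrate lifespan fingerprinting. Centroid position,
coverage, frequency, and the transition matrix do carry signal, and the
centroid observable attains the largest median ND, mirroring what real
studies report.

## Numerical choices

* K-means convergence is an absolute `|ΔRSS| < 1e-5`, per the stated rule;
  the RSS trace is asserted non-increasing in the tests.
* Cosine similarity with a zero-norm vector is an error everywhere
  (undefined, and a zero-norm centroid signals a degenerate clustering).
* Exhaustive matching iterates permutations in lexicographic order and
  replaces only on strict improvement, so ties return the lexicographically
  smallest permutation; the greedy tie-break picks the smallest (l, l')
  pair.
* Permutation p-values use `>=` (ties exceed) and are stored as `k/R` with a
  `p_lt_1_over_R` flag; `format_p_value()` renders the `< 1/R` convention.
* Seeds: one study-level seed; per-(method, K, session) clustering seeds and
  per-cell permutation seeds are drawn from it once, up front, so adding a
  method or K never silently changes another cell's stream order within a
  run configuration.

## Worked example

```{r example}
spec <- synthetic_spec(n_participants = 4, n_sessions = 4, t_volumes = 300,
                       seed = 7)
study <- generate_study(spec)
res <- run_study(study$sessions, study$manifest,
                 methods = "kmeans", Ks = 4, R = 1000, seed = 8)
res[, c("method", "K", "observable", "nd", "p_value", "sig_05")]
```

The centroid row dominates: its ND is far above 1 with the smallest possible
p-value, while lifespan sits near 1 for the structural reason above.

## Known limitations

* The GMM hard-assignment step errors if a component receives no volumes;
  for heavily overlapping states choose a smaller K or another method.
* Exhaustive matching is O(K!) and is capped at K = 8 by default; K = 9, 10
  use the greedy search, which is an approximation (the tests include an
  instance where it is strictly suboptimal).
* `run_study()` loads all sessions into memory; a 100-participant,
  1150-volume study fits easily, but the permutation caches grow as
  `(N_p N_s)^2` per observable.
* Reported lifespans are in volumes (TR units); conversion to seconds is
  presentation-layer only.
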