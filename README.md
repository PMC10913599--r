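# statedyn

Discrete brain-state dynamics from ROI fMRI time series, and a permutation
test for their test–retest reliability.

## Who this is for

Resting-state fMRI sessions can be summarized — in the spirit of EEG/MEG
microstate analysis — by clustering the acquired volumes: each time point
`x_t` (a vector of N ROI signals) gets a state label in `1..K`, and a session
is then described by its K state centroids plus the statistics of the label
sequence (coverage, frequency of appearance, mean lifespan, transition
probability matrix). `statedyn` is for researchers who want to (a) estimate
such states with any of seven standard clustering methods, (b) compare the
resulting state-transition dynamics across sessions, and (c) quantify whether
those dynamics are reproducible enough within a person — relative to between
people — to act as an individual fingerprint.

## The statistic at the core

For a rectangular study of N_p participants × N_s sessions and an observable
`q(p, s)` with pairwise discrepancy `d̃`, the **normalized distance** is

    ND(q) = mean d̃ between participants (same session index)
            -----------------------------------------------
            mean d̃ within participants (all session pairs)

with N_s·N_p(N_p−1)/2 between-participant and N_p·N_s(N_s−1)/2
within-participant pairs. ND > 1 means the observable is more consistent
within than between individuals. Significance comes from a permutation test:
shuffle the N_p·N_s payloads uniformly across cells, recompute ND, repeat R
times (default 10⁴); the one-sided p-value is the fraction of replicates with
ND′ ≥ ND, and zero exceedances are reported as `p < 1/R`.

Before any comparison, the K states of two sessions are matched by the
bijection maximizing the mean cosine similarity of their centroids
(exhaustive over K! permutations for K ≤ 8, greedy above). The matched
observables are then compared by: `1 − mean cosine` for centroid position
(range [0, 2]), total variation for coverage/frequency/lifespan, and the
Frobenius distance for transition matrices.

## Worked example

Generate a synthetic 4-participant × 4-session study with latent Markov
state dynamics (participant-specific centroid rotations and transition
matrices), cluster every session with K-means at K = 4, and run the ND
permutation test for all five observables:

```r
library(statedyn)

spec  <- synthetic_spec(n_participants = 4, n_sessions = 4,
                        t_volumes = 300, seed = 7)
study <- generate_study(spec)
res   <- run_study(study$sessions, study$manifest,
                   methods = "kmeans", Ks = 4, R = 1000, seed = 8)
res[, c("method", "K", "observable", "nd", "p_value", "sig_05")]
#>   method K observable     nd p_value sig_05
#> 1 kmeans 4   centroid 15.238   0.000   TRUE
#> 2 kmeans 4   coverage  1.196   0.026   TRUE
#> 3 kmeans 4  frequency  1.324   0.005   TRUE
#> 4 kmeans 4   lifespan  0.930   0.800  FALSE
#> 5 kmeans 4 transition  1.102   0.030   TRUE
```

Reading the output: the centroid observable has ND ≈ 15 — between-participant
centroid sets are fifteen times more dissimilar than within-participant ones
— with p below the 1/R resolution (printed 0.000, reported as `p < 0.001` by
`format_p_value()`), so state *topography* fingerprints individuals sharply.
Coverage, frequency, and the transition matrix carry weaker but significant
signal. Lifespan sits at ND ≈ 0.93: in this generator every participant
shares the same dwell probability, so lifespans carry no participant-specific
signal by construction (see the vignette).

Per-session summaries come from the same objects:

```r
part <- estimate_states(study$sessions[[1]]$data, 4, "kmeans", seed = 1)
session_observables(part)
#> <session_observables> K=4
#>  coverage:  0.257 0.177 0.3 0.267
#>  frequency: 0.0933 0.0833 0.113 0.08
#>  lifespan:  2.75 2.12 2.65 3.33
gev_total(study$sessions[[1]]$data, part)
#> [1] 0.7070057
```

A total global explained variance of ≈ 0.71 at K = 4 says the four centroids
capture ~71% of the (GFP-weighted) directional variance — the regime the
generator's noise level is calibrated to.

Real data enter through delimited text matrices (one row per volume, one
column per ROI) and a manifest CSV with header `participant,session,file`;
see `load_manifest()`, `load_session()`, and `apply_treatment()` for the
global-signal treatments. A command-line interface wrapping the same
functions is installed at `system.file("cli", "statedyn", package =
"statedyn")` with subcommands `simulate`, `preprocess`, `cluster`,
`observables`, `compare`, `reliability`.

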