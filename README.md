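# spacebytime

Space-by-time decomposition of signed single-trial multichannel time
series — epoched EEG/MEG above all — with single-trial decoding,
decoding-driven model-order selection, cross-subject component clustering,
and a sliding-window LDA baseline.

## The problem and the model

Event-related M/EEG analyses usually average trials, discarding the
single-trial variability that links brain activity to behaviour. This
package represents every trial `n` (a `T x S` matrix of time frames by
sensors) with one shared dictionary:

    M_n  ≈  W_tem  H_n  W_spa

* `W_tem` (`T x P`): non-negative temporal components — unimodal activation
  bumps that say *when* a process is active;
* `W_spa` (`L x S`): non-negative spatial components — sparse sensor
  clusters that say *where*;
* `H_n` (`P x L`): signed per-trial coefficients `h[i,j]` that combine
  temporal component `i` with spatial component `j` — the carriers of all
  single-trial and condition information.

Because M/EEG data are signed, the components are fit with sample-based
cluster non-negative matrix tri-factorization (scNM3F): cluster-NMF
multiplicative updates applied to the two tensor unfoldings handle the
positive and negative parts of the data separately and push components
towards sparse, near-orthogonal cluster indicators, while per-trial
coefficients come from the pseudoinverse least-squares rule
`H_n = pinv(W_tem) M_n pinv(W_spa)`. Conditions are then decoded from the
coefficients with Fisher LDA, leave-one-out cross-validation and ROC area
(Az), with label-permutation significance tests; the numbers of components
`(P, L)` are chosen by stepwise decoding gain; components are compared
across subjects by correlation-based average-linkage clustering with a
subject-uniqueness tree cut.

## A worked example

```r
library(spacebytime)

gt  <- make_ground_truth(seed = 1)   # desk-scale planted EEG-like structure:
x   <- generate_trials(gt)           # 200 trials x 200 frames x 30 sensors
fit <- scnm3f(x, p = 3, l = 2, seed = 1)
fit
#> scNM3F space-by-time decomposition: 3 temporal x 2 spatial components
#>   200 trials, 200 time frames, 30 sensors
#>   total squared error 352.9 (relative 16.836%), 404 iterations

sort(peak_centers(fit))              # temporal component peak latencies (ms)
#> [1] 152 252 452

decode(fit, contrast = c("car", "face"), n_perm = 500, seed = 2)
#> decoding Az = 0.966 (null 95th pct 0.570, p = 0.001996, 500 permutations)
#>   coefficients: h[1,1] h[1,2] h[2,1] h[2,2] h[3,1] h[3,2]
```

The relative error settles at the injected noise floor (the generator runs
at signal-to-noise 5, i.e. 1/6 ≈ 16.7% of the energy is noise), the three
recovered temporal bumps peak within one frame of the planted 150/250/450
ms latencies, and the coefficients decode the planted face/car contrast at
Az ≈ 0.97 against a chance-level permutation null — on par with the 0.95 of
the Bayes-optimal decoder on the true coefficients (cross-validated Az
fluctuates around the oracle value from seed to seed).

Model-order selection and the baseline:

```r
select_dimensions(x, contrast = c("car", "face"), max_p = 6, max_l = 4,
                  seed = 3)$chosen
#> p l
#> 3 2
sapply(sliding_lda(x, contrast = c("car", "face"),
                   centers = peak_centers(fit), duration = 60), `[[`, "az")
```

A thin command-line interface over the same functions lives in
`inst/cli/spacebytime.R` (subcommands `simulate`, `fit`, `decode`,
`select`, `cluster`, `baseline`, `run`), and `run_pipeline()` drives the
whole workflow from one YAML/list configuration with a single seed.

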