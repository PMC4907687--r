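---
title: "Space-by-time decomposition of single-trial M/EEG activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-by-time decomposition of single-trial M/EEG activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacebytime)
```

## The model

Epoched M/EEG data form, per trial $n$, a signed matrix $M_n$ of $T$ time
frames by $S$ sensors. The space-by-time decomposition approximates every
trial with the same small dictionary of non-negative components,

$$M_n \approx W_{tem}\, H_n\, W_{spa}, \qquad n = 1,\dots,N,$$

where the columns of $W_{tem}$ ($T \times P$) are temporal components
("when" something happens), the rows of $W_{spa}$ ($L \times S$) are spatial
components ("where" it happens), and $H_n$ ($P \times L$) holds signed
scalar coefficients $h_n^{i,j}$ that switch each (temporal, spatial) pair on
or off — with either polarity — in the individual trial. The components are
trial-invariant; all single-trial and condition information is carried by
the coefficients. Dimensionality reduction is effective when
$P L \ll T S$.

Classical NMF requires non-negative data and would have to rectify away the
sign changes that carry much of the physiology. The fitting algorithm
(scNM3F, sample-based cluster non-negative matrix tri-factorization)
therefore borrows the cluster-NMF device: a signed matrix $M$ is
approximated by $M W^\top W$ with $W$ non-negative and pushed towards
orthogonality, so $W$ behaves like a soft cluster indicator and the update
rules consume the positive and negative parts of the data separately,
$A^{\pm} = (|A| \pm A)/2$. Applied to both unfoldings of the trial tensor —
$M_{tem}$ of size $T \times SN$ and $M_{spa}$ of size $TN \times S$ — this
gives multiplicative updates (shown here for the temporal factor, with
$A = M_{tem} M_{tem}^\top$):

$$W \leftarrow W \circ
\left[\frac{A^+ W + W W^\top A^- W}{A^- W + W W^\top A^+ W}\right]^{\gamma}.$$

Each iteration performs the spatial update, the temporal update, and then
refreshes every $H_n$ with the least-squares solution
$H_n = W_{tem}^{+} M_n W_{spa}^{+}$ (Moore–Penrose pseudoinverses), which
minimizes the total squared reconstruction error
$E^2 = \sum_n \lVert M_n - W_{tem} H_n W_{spa} \rVert_F^2$ for fixed
components. The loop stops when the relative decrease of $E^2$ falls below a
tolerance.

### Numerical choices

* **Update exponent $\gamma$.** The cluster-NMF literature derives the
  update with a square root on the ratio; the package defaults to
  $\gamma = 0.5$ and exposes $\gamma = 1$ (`update_exponent` in
  `scnm3f_control()`).
* **Stabilizer.** `eps = 1e-12` is added to update denominators to avoid
  0/0; it perturbs fixed points only at the $10^{-12}$ level.
* **Initialization.** $W$ entries are i.i.d. uniform on $(0, 1]$; $H$ is
  immediately set by the least-squares rule. `n_restarts` random restarts
  are run (default 5) and the restart with the lowest final error kept. An
  alternative restart selector (`restart_selection = "decoding"`) keeps the
  restart whose coefficients best decode a designated contrast.
* **Best-iterate return.** The loop alternates two self-reconstruction
  objectives and the coefficient refresh, so monotone descent of $E^2$
  cannot be guaranteed; the fit tracks the best iterate seen and never
  returns a worse solution than it has visited. The stored `error_trace`
  lets users inspect convergence (in practice the trace plateaus).
* **Stopping.** Relative error decrease below `tol = 1e-6`, or `max_iter =
  500` iterations.
* **Degenerate components.** An all-zero column/row is re-initialized from
  uniform noise once; a second collapse aborts that restart with a
  diagnostic. Multiplicative updates cannot revive an exactly zero
  component, hence the explicit guard.
* **Pseudoinverse vs transpose.** Near-orthogonality emerges during
  fitting, so transposes approximate the pseudoinverses; `use_pinv = FALSE`
  selects the cheaper variant. The default keeps the exact least-squares
  rule. Internally the pseudoinverse coefficients are evaluated through the
  Gram identity $W^{+} = (W^\top W)^{+} W^\top$ and the error through its
  trace expansion, so each iteration touches the data matrix only once;
  unit tests pin this fast path to the literal formulas.
* **Scale ambiguity.** $W$ columns and $H$ can trade scale freely. By
  default components are returned as fitted; `normalize = TRUE` rescales
  them to unit norm with compensating rescaling of $H$.

## Decoding and significance

Condition information is read out of the coefficients with a Fisher linear
discriminant: weights $\Sigma^{-1}(\mu_1 - \mu_0)$ from the pooled
within-class covariance, a midpoint bias, leave-one-out cross-validation,
and the area under the ROC curve ($A_z$, the probability that a random
positive trial outscores a random negative one, ties counted half). Scores
from all left-out folds are pooled into a single ROC — a convention this
package fixes explicitly.

A small ridge ($10^{-6}\,\mathrm{tr}(\Sigma)/d$) keeps the covariance
invertible at low trial counts; it is computed once per feature matrix and
reused in every fold so all folds share one score scale. The leave-one-out
scores are computed exactly by rank-one Sherman–Morrison downdates of the
pooled scatter ($O(N d^2)$ total), and the test suite verifies equality
with the literal per-fold refit.

Significance uses label permutation: trial labels are shuffled (500 times
by default), the full cross-validated pipeline is rerun per shuffle, and
the add-one p-value $(1 + \#\{A_z^{null} \ge A_z\})/(n_{perm}+1)$ is
reported; performance is significant when the observed $A_z$ exceeds the
95th percentile of the null.

## Choosing the numbers of components

Starting from $(P, L) = (1, 1)$, the selector alternately tries adding one
temporal or one spatial component. Each candidate is refit from scratch
(avoiding warm-start path dependence) and its decoding gain is tested by
permuting only the coefficient block of the added component across trials,
leaving all other coefficients intact. A candidate is accepted when its
observed $A_z$ beats the 95th percentile of that null *and* exceeds the
current model's $A_z$. The second condition matters: a redundant extra
component — say, a planted bump split in two — is individually informative,
so permuting it degrades decoding and the permutation test alone rejects
its null even when the candidate decodes no better than the current model;
requiring a positive gain stops the search at the planted dimensionality in
our simulations rather than overshooting. When both increments are
significant the larger gain wins, with ties to the temporal side; at
`alpha = 1` every increment passes and the search degenerates to running to
its bounds. Selection refits default to 2 restarts: candidate ranking by
decoding proved robust to restart count, and refits dominate the runtime of
the search.

The added component's coefficients are permuted as one block per trial
(rather than column by column), matching the view that the new component is
a single unit of the model.

## Cross-subject component clustering

Components of one kind from several subjects are compared as plain vectors
(length $T$ or $S$) by Pearson correlation on the raw values — no z-scoring,
since non-negative component profiles are directly comparable — and grouped
by average-linkage (UPGMA) agglomeration on the distance $1 - r$. The tree
is cut at the smallest number of clusters for which no cluster contains two
components from the same subject; cluster means serve as group-level
representatives. Ties in the cut use the dendrogram's standard monotone
partition for determinism.

## The sliding-window baseline

The conventional comparison decodes sensor values directly: 60 ms windows
centered on the peaks of the fitted temporal components, sensor activity
time-averaged within each window (one spatial weight vector per window),
then the identical LDA/LOOCV/$A_z$/permutation machinery. Windows are
clipped at epoch edges rather than erroring. With a one-frame window and
coefficients constructed to equal the windowed sensor values, the two
decoders are algebraically identical — a compositionality check in the test
suite.

## What the synthetic generator emulates — and what it does not

`make_ground_truth()` + `generate_trials()` produce data with exactly the
structure the model assumes: unimodal non-negative Gaussian temporal bumps,
sparse spatial loadings on disjoint sensor clusters, signed
condition-dependent coefficients $H_n = M_c + \sigma_H Z$, and white
observation noise. Defaults are a desk-scale emulation of a two-condition
(face/car) visual categorization EEG experiment:

* 200 frames at 250 Hz spanning −100 to +696 ms around stimulus onset, 30
  sensors (the full experimental scale, 700 frames at 1 kHz over 60
  sensors, is reachable through the arguments);
* three temporal bumps peaking at 150, 250 and 450 ms (sd 40 ms), two
  disjoint ten-sensor clusters;
* 100 trials per condition; coefficient noise $\sigma_H = 0.5$ around a
  canonical mixed-sign mean pattern; observation noise set from a
  signal-to-noise ratio of 5.

Two generator design points deserve note. The class separation
$\lVert M_{face} - M_{car} \rVert = \Phi^{-1}(0.95)\sqrt{2}\,\sigma_H$ is
calibrated so the Bayes-optimal decoder on the true coefficients has
$A_z \approx 0.95$, and it is spread over cells touching every planted
component ((1,2), (2,1), (3,2)) so that each temporal and each spatial
component carries part of the condition information — concentrating it in
one spatial column would make a single spatial component sufficient for
decoding and dimensionality selection could not see the second one. The
canonical mean pattern is deliberately well-conditioned with only mildly
correlated rows: in exploratory runs, rank-deficient or strongly
anti-correlated condition means reproducibly trapped the multiplicative
updates in poor local optima, and we consider such means a degenerate
design rather than a target condition.

The generator does **not** emulate real EEG physics: no volume-conducted
mixing or head geometry, no 1/f or oscillatory background, no temporal
autocorrelation of noise, no artifacts, no inter-subject variability beyond
what the user injects. Passing tests therefore demonstrate correctness of
the algorithms under the model's own assumptions, not performance on real
recordings.

## Problem sizes used by the test suite

The recovery, decoding, selection and clustering studies in the automated
tests run at the desk scale above (and smaller fixtures for unit tests):
noiseless and SNR-5 recovery over 20 seeds, permutation size over 200
simulated null datasets ($N = 100$, $d = 6$, 500 permutations), selection
over 20 planted and 20 null runs, and 10 simulated subjects for
clustering. These sizes keep the full suite comfortably reproducible on a
single CPU while leaving each study enough replicates for its binomial
acceptance bands.

## Known limitations

* Convergence of the alternating updates has no formal proof (two coupled
  objectives); the best-iterate guard and restarts are pragmatic defenses.
* The decomposition has inherent permutation and scale ambiguities;
  component identity across fits is only defined up to matching
  (`match_components()`).
* Decoding is strictly binary; multiclass contrasts must be decomposed into
  pairwise questions.
* The selection search is greedy and forward-only; it will not revisit an
  accepted increment.
* File I/O uses a self-describing plain-text dialect (TSV body with a JSON
  header line, label CSVs, decomposition directories); it is lossless to 15
  significant digits but not a binary scientific container format.

## A worked desk-scale run

```{r example, eval = FALSE}
gt <- make_ground_truth(seed = 1)      # desk-scale study conditions
x <- generate_trials(gt)
fit <- scnm3f(x, p = 3, l = 2, seed = 1)
summary(fit)
peak_centers(fit)                      # ~150/250/450 ms
decode(fit, contrast = c("car", "face"), n_perm = 500, seed = 2)
select_dimensions(x, contrast = c("car", "face"),
                  max_p = 6, max_l = 4, seed = 3)   # chooses (3, 2)
```
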