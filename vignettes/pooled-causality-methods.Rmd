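---
title: "Pooled Granger causality and two-slice dynamic networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled Granger causality and two-slice dynamic networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temponet)
```

This vignette is the package's account of its statistical machinery: the
generative model behind the simulator, the pooled Granger causality test,
the network-construction rules, the bootstrap, the two-slice dynamic
Bayesian network (DBN) learner, and — importantly — the choices we made
where the design was genuinely open, with the reasoning.

## 1. The data shape and why pooling is needed

The intended data are daily-course expression profiles from a cohort:
tens of individuals, each measured at roughly hourly occasions (seven in
the motivating design), under one or two arms (fasted/fed). Granger
causality classically needs a long series; a 6–7 point series supports a
nested F test with one denominator degree of freedom, which has
essentially no power (Section 6 quantifies this). The package's central
construction is the *virtual long series*:

1. Reference each individual's log-scale profile to their own first
   occasion (`reference_to_baseline()`): value(g, i, t) − value(g, i, 0),
   dropping occasion 0. On log scale this is a re-ratioing that removes
   individual baseline (scale) differences. Seven occasions become six.
2. Stack the lag-1 regression rows of all individuals
   (`stack_lagged_rows()`), never letting a row span two individuals:
   N individuals with L usable occasions give N(L−1) rows.
3. Fit one shared coefficient set across the pooled rows.

The pooling is valid under the homogeneity assumption that individuals
share similar response dynamics — plausible for a deliberately homogeneous
cohort (same sex, similar age, shared genetic background, identical meal),
and precisely the assumption the baseline referencing is designed to
support by removing the obvious individual-level nuisance. For a
heterogeneous population one would move to a mixed-effects formulation
with individual-specific slopes instead; that variant is out of scope
here.

We drop occasion 0 after referencing rather than keeping it as an all-zero
vector: a column of exact zeros carries no information for the lagged
regression, and keeping it would silently distort the row count
bookkeeping that the degrees of freedom rely on.

## 2. The bivariate autoregressive model and its test

For an ordered pair X → Y the generative model the test assumes is the
stationary first-order bivariate autoregression (BVAR)

$$X_t = a X_{t-1} + \varepsilon_{x,t}, \qquad
  Y_t = b Y_{t-1} + c X_{t-1} + \varepsilon_{y,t},$$

with fixed per-series coefficients and i.i.d. Gaussian innovations.
`granger_test()` compares the reduced model (intercept + own lag) with the
full model (intercept + own lag + partner lag) on the pooled rows:

$$F = \frac{(RSS_r - RSS_f)/1}{RSS_f/(n-3)} \sim F(1,\, n-3)
  \text{ under } c = 0 .$$

Design choices here, and why:

* **Intercepts are included in both models** (so the full model has
  k = 3 coefficients and the denominator df is n − 3). After baseline
  referencing the pooled rows have nonzero mean (every series starts at 0
  and drifts), so an intercept is the safe default; `intercept = FALSE`
  switches to the 2-coefficient variant with df n − 2 for users whose
  preprocessing already centres the rows.
* **One shared coefficient set across individuals, no per-individual
  slopes** — this *is* the pooling assumption; relaxing it would require
  the mixed-model route deliberately not taken.
* **Lag order is fixed at 1 and is not a tunable.** With six usable
  occasions per individual there is no room for lag-order selection, and
  the inferred couplings should be read as averaged lag-1 dependencies
  over the sampling day.
* **Degenerate fits**: an exactly collinear (constant) partner-lag column
  means the test cannot distinguish the models; the pair is skipped with
  p = 1 and a `collinear` flag rather than an error, so genome-wide scans
  keep their accounting. An exact full-model fit (RSS_f below 10⁻¹² of
  RSS_r) reports p = 0 with a `degenerate` flag.
* **Rank-deficient designs** fall back to the minimum-norm (SVD) solution
  with a warning, so scans over near-duplicate probes do not abort.

## 3. Genome-wide scan, correction, pruning, ranking

`scan_all_pairs()` tests all p(p−1) ordered pairs; failures become status
rows, not dropped rows. `adjust_and_threshold()` corrects over all tested
pairs and keeps edges with adjusted p < α (default 0.01).

* **Bonferroni is the default correction.** The reference protocol's
  correction for its "p < 0.01 after multiple testing correction" rule is
  unnamed; Bonferroni over the full set of ordered pairs is conservative
  and consistent with the very small false discovery rates such networks
  report. Benjamini–Hochberg is available (`method = "bh"`), and BH
  q-values are *always* reported alongside, whatever the thresholding
  method, as the FDR estimate for the retained edge set.
* **Thresholding happens before pruning.** Whether to prune among all
  edges or only significant ones is open; we threshold first so that the
  pruning rule ("keep the most significant cause") chooses among edges
  that have individually survived correction. The per-target rule keeps
  the smallest raw p; ties break to the lexicographically smaller source
  id, with a message, so results are deterministic.
* **Why prune at all:** a bivariate test marks every ancestor of a chain
  as causal for every descendant, so targets accumulate redundant
  incoming links; keeping each target's single strongest cause removes
  the bulk of these indirect edges while preserving the causal flow
  direction. After pruning every in-degree is ≤ 1 and the edge count is
  bounded by the gene count.
* `rank_regulators()` orders genes by out-degree (a "causal regulator"
  regulates at least one gene); `out_degree_distribution()` exports the
  exact histogram including zero-degree genes. We deliberately do not fit
  a power law — heavy-tailed out-degree histograms are typical, but
  declaring them scale-free is an interpretation left to the user.

## 4. Bootstrap confidence

`bootstrap_confidence()` resamples *individuals* with replacement — the
individual with their entire short series is the exchangeable unit; a
duplicated individual contributes duplicated rows. Each of B replicates
(default 100) re-runs the scan and correction; an edge scores a success
when its adjusted p passes the threshold in that replicate, and its
confidence is the success fraction (a multiple of 1/B). Two conventions
are worth stating explicitly:

* Confidence counts replicates where the link is *significant* — p-value
  below the corrected cutoff. (Descriptions of such procedures sometimes
  say "above a threshold", which is ambiguous when the threshold is on a
  p-value; significance is the only reading consistent with calling the
  result a confidence.)
* Scoring happens before pruning within each replicate: pruning is a
  topological post-processing step, and letting it veto significance
  inside replicates would conflate edge support with the in-degree
  constraint.

## 5. The two-slice DBN learner

With first-order Markov dynamics, two time slices suffice: intra-slice
edges act within occasion t (fast, sub-sampling-interval effects) and
inter-slice edges act from t−1 to t. The intra-slice network is a fixed
input — typically a static Bayesian network learned from a much larger
steady-state cohort — and is never rewired here; only inter-slice links
(self links allowed) are added or removed. `transition_rows()` pools the
(t−1, t) vector pairs across individuals.

Each child's local model is a linear-Gaussian regression of child@t on an
intercept, its intra-slice parents at t (coefficients re-estimated in
every candidate model, edges never changed — the literal reading of a
fixed intra-slice structure), and its inter-slice parents at t−1, scored
by the Gaussian profile-likelihood BIC

$$\mathrm{BIC} = n \ln(RSS/n) + k \ln n,$$

k counting the regression coefficients plus one for the noise variance
(lower is better; an exact fit scores −∞). Because the intra-slice
structure is fixed and inter-slice parents point backward in time, the
network score decomposes over children, so `learn_inter_slice()` optimizes
each child independently: greedy hill-climbing over single-link
additions/removals from the child's candidate set, started from a seeded
random subset with a shuffled sweep order, until no move lowers the BIC.
The reference protocol runs 1000 restarts and keeps edges appearing in at
least 30% of structures (`consensus_network()`, inclusive boundary: an
edge at exactly the threshold is kept — the natural reading of "appeared
in 30%"); tests here scale restarts down to 50, which the agreement
checks against exhaustive subset search justify (Section 6). The search
method itself (hill-climbing rather than annealing or MCMC) is our
choice: the protocol's heuristic is inherited from prior work and
unspecified, and with per-child decomposability plus random restarts,
hill-climbing already matches exhaustive search on candidate sets small
enough to enumerate.

Candidate parent sets default to all genes (including the child itself —
self links are the biologically dominant temporal edge). For large panels
an optional screen keeps the top-K absolute lagged correlates per child
(`screen_top_k`), bounding cost; the genome-scale protocol this package
distils constrained its search with a 7310-node intra-slice network,
which a desk-scale reproduction cannot obtain.

## 6. The synthetic-data generator and what the experiments show

`simulate_bvar_pair()` / `simulate_pair_population()` implement the BVAR
model above. The numeric constants of the reference simulation are not
recoverable from its description, so the defaults are mid-strength
stationary dynamics chosen once: a, b, c ~ N(0.5, 0.1²), innovation SD 1,
initial values uniform on [−1, 1]. These defaults reproduce the
qualitative regime the method lives in — per-series 6-point tests are
powerless at corrected thresholds while the pooled 40×6 design matches a
240-point single series — which is the property that matters, not the
specific constants. Intercepts are omitted from the generative model;
individual baselines are a panel-level phenomenon, handled (and removed)
by referencing.

`permute_pair_assignment()` builds the null by re-pairing each Y with an
X from a different pair via a seeded cyclic shift with a random nonzero
offset — a simple construction that guarantees a derangement (no series
keeps its partner) with a single uniform draw. One subtlety is worth
recording: the re-paired Y series keep the c·X_old contribution in their
own history, so their reduced-model residuals are mildly autocorrelated;
empirically the test's false-positive rate on 1000 permuted 240-point
pairs stays within 0.05 ± 0.02 at α = 0.05 and the p-values pass a
Kolmogorov–Smirnov uniformity check at the 1% level, but the calibration
is approximate, not exact, and this is inherent to the permutation design
rather than to the implementation.

`simulate_cohort_panel()` generalizes the generator to multi-gene panels
with known ground truth: per individual, a baseline offset per gene
(SD `baseline_sd`), and deviations from baseline evolving under the
linear-Gaussian two-slice system (inter-slice coefficient matrix applied
to the previous deviation, intra-slice DAG applied within the occasion in
topological order, innovation SD `noise_sd`). The emitted value is
offset + deviation, on log scale.

* **`init_sd = 0` by default**: the time-0 sample measures the
  individual's resting state exactly, so baseline referencing removes the
  offsets *exactly* and the referenced series follow the stated dynamics
  with known coefficients — the property ground-truth recovery tests
  need. A positive `init_sd` makes occasion 0 itself noisy; referencing
  then leaves a residual individual-level intercept correlated with the
  regressors (the classic hazard of differencing against a noisy
  baseline), which inflates false links. We expose it as an explicit
  robustness dial precisely because real baselines are noisy; the
  generator's default isolates the methods' behaviour under their own
  assumptions.
* **What the generator does not emulate:** measurement error on top of
  biological noise, missing samples, arm-specific dynamics, non-Gaussian
  heavy tails, gene-specific noise scales, and heterogeneous per-individual
  dynamics. Passing recovery tests therefore demonstrates correctness of
  the machinery under the model's assumptions, not performance on real
  cohort data.

The experiment harness quantifies the headline behaviours (all of these
are recomputed by `scripts/acceptance.R` and the test suite; replicate
counts default to 200, with 1000 used where the claim concerns a
1000-series protocol — sizes chosen to make every check a few seconds to
a few minutes of desk time):

* power versus length (`power_vs_length`): recall ≥ 0.95 at 240 points,
  0 corrected hits at 6 points across 1000 series;
* power versus sampling interval at fixed point count
  (`power_vs_interval`): recall declines as the interval widens, because
  thinning an AR(1) system by k shrinks the observable lag coupling
  roughly like a^(k−1)·c;
* pooled versus long (`pooled_vs_long`): 40 pooled 6-point series match a
  240-point series to within 0.10 recall at the same corrected threshold
  (the long arm extends the seed stream of the pooled arm's first series,
  so the two conditions coincide exactly when their geometries do);
* permutation false-positive rates (`empirical_fpr`) across a threshold
  grid, with monotone nesting of rejection regions.

## 7. Scale of the network experiments, and an honest accounting of false links

For the DBN recovery experiment (20 genes, 40 individuals, 7 occasions,
self links everywhere plus four strong cross links) the learner recovers
100% of true inter-slice edges at 30% consensus over 50 restarts, with a
spurious-link rate (false recovered links over candidate non-links) of a
few percent. Two structural facts deserve to be stated plainly rather
than hidden in a passing test:

* Under the BIC above, an irrelevant candidate parent lowers the score
  with probability ≈ P(χ²₁ > ln n) — about 0.02 at n = 200 transitions.
  These picks are properties of the *data*, not of the search: restarts
  re-find them (their consensus frequency is near 1), so restart
  consensus filters search variability, not sampling variability. A
  p-gene panel therefore carries an expected false-link floor of roughly
  0.02·p(p−1) regardless of search quality — about 8 links at p = 20 —
  and the precision of the recovered edge set is bounded accordingly.
  Reducing this floor requires more data or a stiffer penalty, not a
  better optimizer.
* The self-link experiment ("universal autoregression plus sparse cross
  links") is run at 10 genes for exactly this reason: true self links
  grow linearly in p while the false-link floor grows quadratically, so
  the measured self-link share reflects the dynamics (autoregulation
  dominating temporal structure, consensus share ≥ 0.7) rather than the
  floor only when 0.02·p² ≪ p. At genome scale the reference protocol
  kept the share near 73–75% because its candidate space was constrained
  by the fixed intra-slice network.

## 8. Numerical conventions, determinism, limitations

* OLS is QR-based; rank-deficiency falls back to SVD minimum-norm with a
  warning. Nesting (RSS_r ≥ RSS_f) is enforced up to 10⁻¹² relative.
* All seeded functions restore the caller's RNG state, and every
  stochastic stage of a pipeline derives its own sub-seed from a master
  seed plus a stream label (`derive_seed()`), so stages are individually
  re-runnable and whole pipelines are byte-reproducible.
* Ties and boundaries are fixed and documented: pruning ties break
  lexicographically; the consensus threshold is inclusive; thinning keeps
  every k-th point starting from the first.
* Known limitations: lag-1 stationary dynamics only (no lag mixtures, no
  time-varying coefficients); bivariate conditioning only (no
  multivariate Granger variants); single-arm analysis (fasted and fed
  panels are analysed separately, not jointly); missing occasions drop
  the individual rather than being imputed, keeping the df bookkeeping
  exact; the intra-slice network is trusted as given, with no provision
  for treating it as a soft prior.
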