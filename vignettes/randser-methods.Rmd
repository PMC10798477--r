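---
title: "Measuring and modelling randomness in human-generated binary series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling randomness in human-generated binary series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(randser)
```

## The problem

When people are asked to "imagine a fair coin and report the outcomes",
the series they produce deviate from a Bernoulli process in systematic
ways: alternations are over-produced (rates of 0.6–0.7 rather than 0.5),
runs are under-produced, and the quality of the output decays over the
course of the task.  `randser` provides the three ingredients needed to
study this quantitatively:

1. an **objective randomness measure** for short binary strings, based on
   algorithmic (Kolmogorov–Chaitin) complexity estimated by the Coding
   Theorem Method (CTM) and extended by the Block Decomposition Method
   (BDM);
2. a **process model** of random-like series generation built on working
   memory: a bounded buffer of recent choices, a schema that proposes the
   next element, a complexity-based randomness judgment, and fatigue; and
3. the **statistical layer** used to analyse such experiments: rank-sum
   tests, inverse-variance weighted least squares, and a penalized-spline
   mixed trend model with a condition-difference smooth and permutation
   inference.

A synthetic-cohort generator ties the three together so that the whole
pipeline — generation, scoring, exclusion filtering, analysis — can be
exercised end to end without any external data.

## The complexity table

### Coding Theorem Method

The algorithmic complexity of a short string cannot be computed directly,
but it can be estimated from the output distribution of a space of small
Turing machines: if a fraction `f(s)` of halting machines outputs `s`,
then `K(s) = -log2(f(s))` bits.  `ctm_enumerate()` runs this enumeration
exhaustively for the space of `n`-state, 2-symbol machines in the
standard `(4n+2)`-transition formalism, with machines started on a blank
tape, a runtime cap at the busy-beaver bound (so no halting machine is
missed), and the output distribution symmetrised over string reversal
(mirror machines) and bit complementation (blank-1 runs).  A reduced
enumeration — the first transition fixed up to symmetry and state
relabelling — cuts the work by a factor of about nine: the packaged
table required 1.22e9 machine runs of the (4,2) space (about 15 minutes
of CPU), standing for the full space of 1.1e10 machines.

The packaged resource `ctm-b2-d12-m4.tsv` stores the resulting values
for every binary string of length 1–12 (8190 entries, stored as 4095
complement-reduced rows with an md5 manifest).  The (4,2) space covers
every string up to length 8 and progressively fewer beyond (95% of
length 9, 40% of length 10, 12% of length 11, 3% of length 12).

Strings the space never outputs are *completed*: an unobserved output
has frequency below that of every observed string of its length, so its
complexity must exceed all of theirs; within the unobserved set, a
recursive minimal two-split rule (`min K(u) + K(v)` over `s = uv`)
provides the ordering, and the whole set is shifted to sit a quarter bit
above the observed maximum of its length class.  Both enumeration
symmetries survive the completion exactly.

Two structural facts about this table matter downstream:

* **Constant strings are the most frequent outputs only up to length 8.**
  Writing a long all-zero stretch and then halting requires counting
  steps, which small machine spaces cannot do without tape marks, so at
  lengths 9+ some non-trivial strings are more frequent than the
  constant.  The min–max normalization is therefore *anchored at the
  constant string* (which maps to exactly 0, with clamping below), not at
  the table minimum.
* **Lengths 1 and 2 are degenerate**: every output of those lengths is
  exactly equally frequent, so normalization refuses them.  No analysis
  in the package normalizes below length 3.

The published table behind the original analyses was computed from the
far larger (5,2) space; it is not redistributable here, and the two
tables genuinely differ.  On the two classic worked examples, this table
gives normalized complexities of 0.491 for `010101` and 0.523 for
`101001` — the same ordering as the published values (.542 and .647) at
visibly different magnitudes.  All package results are therefore
internally consistent with the packaged table rather than numerically
interchangeable with analyses based on the (5,2) table.  The miniature
(2,2) space (instantaneous to enumerate) is used in the test suite as a
sanity oracle for the construction logic.

### Measures

* `ctm(s)` — exact lookup, lengths 1–12, in bits.
* `bdm(s, block_size)` — non-overlapping blocks with a trailing
  remainder discarded ("ignore" boundary dialect);
  `sum over distinct blocks (ctm(block) + log2(multiplicity))`.
* `normalize_complexity(raw, length)` — min–max rescaling: 0 for the
  constant string, 1 for the most complex achievable value under the same
  decomposition, clamped to `[0, 1]`.
* `overall_complexity(series)` — mean normalized CTM over step-1 sliding
  chunks of length 11 (the "chunks of 11" convention; a disjoint-chunk
  dialect is available behind an argument).  Sliding windows avoid
  discarding a remainder on the 103–120-element series typical of the
  task.
* `rolling_complexity(series, window_w)` — the dynamic measure: a vector
  of normalized complexities over windows of width 5–9 (7 by default,
  matching the comparison task's string length); positions are reported
  as 0-based window END indices.

## The generation model

`generate_series()` implements one element per stimulus:

1. **Propose.** With an empty buffer, a fair draw.  Otherwise the active
   schema proposes an *alternation* of the previous symbol with
   probability `theta` (default 0.65, inside the 0.6–0.7 band that
   people judge most random) and a repetition otherwise.
2. **Judge.** The buffer extended by the candidate is compared with the
   buffer extended by the opposite symbol, both truncated to the last
   `k` symbols (`k` = working-memory capacity, nominally 5–9) and
   normalized for their own length.  With probability `p_t` the judgment
   is veridical — accept iff the candidate's window is at least as
   complex (ties accept) — otherwise it degrades to a fair coin flip.
   This two-candidate rule is the minimal operationalization of
   "evaluate whether the addition would increase randomness" that
   terminates with a binary alphabet: a rejected candidate simply makes
   the opposite symbol the answer.
3. **Fatigue.** `p_t = floor + (p0 - floor) * exp(-lambda_eff * t)`,
   with `lambda_eff = lambda * (1 + kappa)` when the recent elements are
   *not* displayed (the invisible condition) and `lambda` when they are.
   The floor defaults to 0.5 — a fully fatigued judgment is a coin flip.
   Visibility does not change the buffer content (the display mirrors
   exactly the last `k` elements); it only relieves the storage load,
   which is how the model realizes "offloading storage frees processing
   resources".
4. **Update.** The emitted symbol enters the buffer; the oldest symbol
   beyond capacity is dropped.  With probability `omission_prob` the
   stimulus is missed entirely (nothing emitted, fatigue still advances),
   which is what makes real series 103–120 elements long rather than
   exactly 120.

Two behavioural instruments are simulated against the same table:
`simulate_comparison_responses()` answers the 64-pair comparison task
(choose the more complex of `prefix+0` vs `prefix+1`) with probability
`plogis(alpha + gamma * gap)`, and `simulate_span_test()` runs the
adaptive complex-span procedure (trials start at 2 letters, grow on
success, stop after two consecutive failures; letter-level recall
probability `plogis(a * (c - m))`), scored by the partial-credit
convention (total letters recalled in position, failed trials included).

## The synthetic cohort

`generate_cohort()` draws a population in which a single latent ability
`z ~ N(0,1)` is coupled, through a Gaussian copula with correlation
`rho = 0.8`, to comparison discrimination `alpha`, span capacity `c`,
initial judgment accuracy `p0` (marginal Beta(8,2)) and — negatively —
fatigue rate `lambda` (marginal Gamma(2, scale 0.005)).  Capacity `k`
(uniform on 5–9) and alternation bias `theta` (Beta(6.5, 3.5)) are
independent draws.

`k` is deliberately left out of the ability couple.  Under the packaged
table, the generation model's judgment and the complexity measure share
the same lookup values, and a small-capacity agent optimizing its short
window drifts into patterns the machine space rarely outputs — which the
measure then scores as highly complex.  The net effect of `k` on overall
complexity is strong and positive between `k = 3` and `k = 9` (the
directional contract of the capacity hypothesis, which the tests
assert), but flat-to-weakly-negative inside 5–9.  Routing the ability
correlation through `p0` and `lambda` instead yields the designed
positive complexity–correctness and complexity–span associations at the
empirically reported magnitudes (weighted R-squared means of roughly
0.13 and 0.04 across seeds in the calibration runs reproduced by the
test suite) without asserting a within-5–9 capacity gradient this
synthetic world does not have.

Completion times (lognormal around 10.5 min with a 5% outlier mass) and
per-participant omission rates (Beta(1.3, 12)) are calibrated so that the
published absolute exclusion rules — series shorter than 103 elements;
completion time outside [7.5, 15] minutes; processing accuracy below
85%; span score below 4 or above 10 — each remove a realistic fraction
(about a quarter of a Study-1-style cohort and about 30% of a
Study-2-style cohort survive removal at rates comparable to the original
reports).  Filters apply the printed absolute cut-offs, in published
order, with inclusive boundaries ("less than 103" keeps 103); a
percentile mode re-derives the 10% bounds from the cohort at hand.

`recover_parameters()` closes the loop: a grid-search maximum
pseudo-likelihood over `(k, lambda_eff)` per condition group, scoring
each observed transition against the model's closed-form emission
probability (judgment indicators from the table, `theta` profiled per
participant, `p0` fixed).  Omissions are not observed in a bare series,
so consecutive emitted symbols are treated as consecutive stimuli — an
approximation that biases `lambda` slightly downward but preserves the
visible/invisible ordering, which is what the recovery checks assert.

## The statistical layer

* `rank_sum_test()` — Mann–Whitney U with midranks; exact conditional
  enumeration for `n1 + n2 <= 16`, otherwise the normal approximation
  with tie and continuity corrections (matching the standard reference
  implementation to 1e-8 in the tests).
* `wls_fit()` — closed-form weighted least squares with the slope CI
  from the t distribution on `n - 2` df and weighted R-squared about the
  weighted mean.  Weights come from `participant_weights()`: the
  reciprocal of each participant's rolling-complexity variance, with
  zero-variance profiles capped at 10 times the 99th percentile of the
  finite weights.
* `fit_trend_model()` — the trend model for rolling-complexity profiles:

  `y_it = b0 + b1 vis_i + f(t) + f_d(t) vis_i + u0_i + u1_i t + e_it`

  with `f` and `f_d` cubic B-spline smooths (dimension `K = 10` by
  default, uniformly spaced knots so the second-difference coefficient
  penalty annihilates exactly constant and linear functions, sum-to-zero
  over the observed grid), subject intercepts and slopes as
  ridge-penalized effects, and all four penalties selected by GCV on a
  log-spaced grid with one half-decade refinement pass.  Subjects must
  share a common grid prefix (rolling profiles of unequal length do);
  per-prefix-length cached cross-products plus a Schur complement over
  the 2x2 subject blocks make one solve cheap enough that permutation
  inference is practical.  Marginal and conditional R-squared follow the
  fixed/random/residual variance partition of the fitted components.
* `permutation_test_difference()` — condition labels are permuted at the
  subject level (the design is between-subject); the statistic is the
  penalized-RSS reduction attributable to the condition terms (jointly,
  and separately for the difference smooth and the linear offset), and
  `p = (1 + #{perm >= obs}) / (B + 1)`.  Two details keep the test
  exact under exchangeability and still powerful:
  the smoothing parameters are re-estimated by GCV under the **null**
  model (no condition terms) and held fixed across permutations —
  selecting the difference-smooth penalty on the observed labelling
  demonstrably inflates the type-I rate — and the subject-effect ridges
  are floored at the half-shrinkage scale, because condition is constant
  within subject and fully flexible subject intercepts would absorb the
  very between-group signal under test.  Both choices depend only on
  the profiles, never on the labels.

The exact reproduction of the original mixed-model F statistics is out
of scope by design: those values depend on one particular smoothing
implementation and on data that were never deposited.  The permutation
machinery answers the same inferential question — is the condition
difference real — with calibration the test suite verifies directly.

## What the tests demonstrate (and at what problem sizes)

* The two worked examples, the 64-pair task combinatorics, exhaustive
  normalization bounds for lengths 5–12, and dual-route agreement
  (string-based naive re-implementations, `wilcox.test`, `lm`, and an
  `mgcv` cross-check of the common smooth) at tolerance 1e-9.
* Parameter recovery: 20 replicate cohorts of 100 agents at `k = 7`
  recover both group estimates in {6, 7, 8}; 20 cohorts with
  `lambda = 0.01, kappa = 1` recover the faster invisible fatigue in
  every replicate.
* Visibility dynamics: with 200 agents per condition
  (`kappa = 4, lambda = 0.022, p0 = 0.95`, 200-element series), the
  invisible condition's fitted early-phase decline (first 30 windows) is
  steeper, and the last-30-window means are statistically
  indistinguishable — the qualitative published pattern.
* Permutation calibration: 200 Monte-Carlo null cohorts (10 subjects per
  condition, `kappa = 0`, B = 199) give a rejection rate within
  [0.02, 0.09] at the 5% level; 20 cohorts at a designed strong effect
  (sustained accuracy separation: `kappa = 39, lambda = 0.005,
  p0 = 0.98`, 25 subjects per condition) give `p <= 0.01` in at least
  95% of replicates.
* End-to-end determinism: byte-identical pipeline outputs under a fixed
  master seed.

These sizes were chosen so the designed effects are unambiguous at
single-run Monte-Carlo noise; they are the package's reference study
conditions, not estimates of the original experiments.

## Limitations

* The packaged table comes from the (4,2) machine space.  Analyses are
  internally consistent, but numeric complexity values are not
  interchangeable with (5,2)-based ones, and the completion of lengths
  9–12 encodes an explicit modelling assumption (unobserved implies
  rarer) rather than measured frequencies.
* The generation model shares its lookup table with the measure; agents
  are therefore mildly "self-referential" optimizers, which is visible
  as the flat capacity gradient inside 5–9 discussed above.
* The synthetic cohort emulates the statistical structure of the real
  experiments (effect directions and magnitudes, exclusion rates,
  series-length distribution), not their psychology: no reaction times,
  no 1/f structure, no individual pattern idiosyncrasies beyond the
  modelled parameters.
* Omission handling in recovery treats emitted symbols as consecutive;
  with the default omission rates this is a small, ordering-preserving
  bias.
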