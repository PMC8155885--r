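---
title: "Multiscale entropy, TRT labelling and bee-colony feature selection: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale entropy, TRT labelling and bee-colony feature selection: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mseabc` implements a pipeline for detecting behaviourally defined
"fast" events — candidate markers of implicit learning — from
multichannel EEG. This vignette explains the science the package
implements, the parameters that matter, and the design decisions taken
where the method leaves room, so that results can be interpreted and
the implementation audited.

## The pipeline at a glance

A session consists of trials of four questions each; an underlying rule
(unknown to the participant) links the fourth question's answer to the
first. If the participant implicitly acquires the rule, the fourth
question's response time (RT) drops persistently below the RTs of the
rule-free middle questions. The pipeline:

1. filters the EEG (0.5--50 Hz band-pass, power-line notch) and splits
   it into clinical frequency bands,
2. cuts one epoch per question (question onset to next question onset),
3. converts each epoch x channel x band into a multiscale sample
   entropy (MSE) profile,
4. labels trials *fast*/*slow* from the RT series via the Triple
   Response Time (TRT) rule,
5. assembles a feature table (one row per labelled trial, one block of
   MSE scales per (channel, band) feature) and balances the classes,
6. selects informative (channel, band) features with a binary
   Artificial Bee Colony (ABC) optimizer whose fitness is
   cross-validated classifier accuracy, and
7. evaluates selected vs. all-features classifiers with
   confusion-matrix metrics, ROC curves and paired t-tests.

## Sample entropy and coarse-graining

Sample entropy of a series $x_1..x_N$ with template length $m$ and
tolerance $r$ is $-\log(A/B)$, where $B$ counts unordered pairs of
length-$m$ templates whose Chebyshev distance is at most $r$, and $A$
counts the same for length $m+1$. Conventions (they matter for exact
values):

* templates of both lengths start at the first $N-m$ positions, so the
  counts are drawn from the same index set and a constant series gives
  $A=B$, i.e. entropy exactly 0;
* self-matches are excluded; the distance test is inclusive ($\le r$);
* the logarithm is natural (nats);
* $A=0$ makes the statistic undefined: the value is flagged `NA` and
  rows containing such entries are dropped at assembly with a reported
  count, rather than substituting an arbitrary cap that would distort
  classification.

Coarse-graining at scale $\tau$ replaces non-overlapping blocks of
$\tau$ samples by their means (trailing remainder dropped). The MSE
profile is sample entropy of the coarse-grained series at scales
$1..\tau_{max}$.

Parameter defaults: $m=2$, $r=0.15\times$SD, $\tau_{max}=20$ — the
standard choices for short biosignals. Two details are fixed
deliberately:

* **r is computed once** from the scale-1 epoch (population SD,
  divide-by-$N$) and reused at every scale. Re-estimating $r$ per scale
  would conflate the variance reduction of block-averaging with genuine
  complexity changes.
* A 3 s epoch at 1000 Hz has 3000 samples, leaving 150 points at scale
  20 — above the ~100-point floor below which sample entropy becomes
  unreliable. `mse_profile()` refuses shorter epochs and names the
  largest feasible scale.

The match counting is implemented in C++ (an $O(N^2)$ pair scan with
early abort); the test suite checks it bit-for-bit against a naive
exhaustive-pair oracle on 200 random sequences.

## Filtering

All filters are zero-phase so epoch timing is preserved.

* Broadband: order-2 Butterworth band-pass 0.5--50 Hz applied
  forward-backward (4th-order magnitude). Channels are demeaned first;
  the startup transient of a zero-mean input is negligible, whereas
  reflection padding would let the junction kink excite the near-DC
  high-pass mode into a slow swell.
* Notch: a zero-phase windowed-sinc FIR band-stop (401 taps, +/-5 Hz
  around the line frequency). A narrow IIR notch at quality factor 30
  has pole radius ~0.996 at 1000 Hz and rings for about a second —
  a third of a 3 s epoch — so an FIR with a strictly finite transient
  is used instead.
* Band split: order-3 Butterworth per band (delta 0.5--4, theta 4--8,
  alpha 8--13, beta 13--30, gamma 30--50 Hz; standard clinical edges,
  gamma capped by the 50 Hz low-pass), forward-backward with
  odd-reflection padding. The outermost edges are treated as *open*
  (delta as a low-pass, gamma as a high-pass): the broadband pre-filter
  already enforces 0.5 and 50 Hz, and filtering those edges twice
  double-attenuates there. With these choices the summed bands
  reconstruct the broadband signal to within ~10--13% RMS on broadband
  noise — a sanity property, not exact, because Butterworth bands are
  not a perfect-reconstruction filter bank.

Independent-component artifact removal is a documented pre-processing
hook, not part of the package: inputs are assumed artifact-cleaned.

## TRT labelling

Per trial, RTs of the four questions are smoothed with a centred
moving median of window 5 (edges truncate to the available neighbours;
missing values are ignored within a window). DRT is the smoothed Q4
RT; URT is the mean of the smoothed Q2 and Q3 RTs. A trial is marked
TRT when DRT has stayed below the lower 90% bound of URT for three
consecutive trials; the mark goes to the third and later trials of each
qualifying run (the moment the criterion completes). TRT trials are
labelled *fast*, the rest *slow*; trials with missing Q2/Q3/Q4
responses are *excluded* and break runs.

**The bound rule is the one genuinely open design point.** "The 90%
negative confidence interval of URT" names a construct, not a formula.
Three readings are implemented (`lower_bound(rule = ...)`):

* `tolerance` (default): a one-sided lower normal *tolerance bound*
  for URT values — rolling mean of smoothed URT minus $k \cdot s$,
  with $s$ the SD of the raw Q2/Q3 RTs in the window and $k$ the
  non-central-t tolerance factor covering 90% of values with 90%
  confidence ($k \approx 2.07$ at $n=10$). Rationale: the detector
  compares a *single* DRT value against the spread of URT values, so a
  value-scale bound is the operative reading.
* `normal_lower`: the mean-scale confidence limit, rolling mean minus
  $1.2816 \cdot s/\sqrt{n}$ on the smoothed URT. This hugs the local
  mean so closely that smoothed DRT noise crosses it roughly half the
  time; because the window-5 median gives the DRT series a correlation
  length of about three trials, the three-in-a-row criterion then adds
  almost no protection and false marks are frequent. It is retained
  for comparison, not as the default.
* `fraction`: $0.9 \times URT$ — simple, but not invariant under
  shifting all RTs by a constant, which the other two rules are.

With the default rule, a planted noiseless Q4 speed-up at trial $L$ is
marked first at exactly $L+2$, and at a 5-sigma effect-to-noise ratio
the first mark stays within $\pm 2$ trials across seeds, while
no-effect series stay mark-free in the large majority of runs (these
are test assertions, recomputed on every run).

Class balancing down-samples the majority class uniformly at random
with an explicit seed, mirroring the balanced 175/175 design of the
motivating study.

## Feature space and encoding

Features are (channel, band) pairs over the nine frontal channels
(AF3, AF4, F3, F4, F5, F6, F7, F8, FZ) and five bands — d = 45 bits,
channel-major order, each bit gating that pair's full MSE profile
(45 x 20 = 900 columns when everything is selected). A factored
encoding (9 channel bits + 5 band bits, d = 14, conjunctive gating) is
available via `feature_space(encoding = "factored")`. Rows use the Q4
epoch's profiles by default — the question governed by the hidden rule
— configurable to concatenate all four questions. Scale-wise bit
selection (bits over individual columns) is deliberately out of scope.

## Binary ABC

A food source is a 0/1 vector over features; fitness is stratified
5-fold cross-validated accuracy of the configured classifier on the
masked table. One iteration runs:

* **employed phase** — every source draws a random neighbour, forms a
  candidate (keep positions where they agree, re-draw disagreeing
  positions 0/1 with probability one half each), and replaces the
  source only on *strict* fitness improvement (ties advance the
  abandonment counter, keeping its semantics well defined);
* **onlooker phase** — as many roulette draws as sources,
  fitness-proportional, each followed by the same greedy step;
* **scout phase** — sources whose abandonment counter strictly exceeds
  `limit` are re-randomized.

Defaults: 20 sources, limit 10, 50 iterations — classical ABC
conventions; the method names these parameters but not their values.
The best-so-far tracker is outside the population, so its curve is
non-decreasing by construction and scout resets cannot lose the
incumbent. All-zero vectors (no features) get fitness 0. Fitness is
cached by bit pattern: the fold assignment is fixed once per run, so
fitness is a pure function of the bits and caching is exact. The
real-valued ABC update (current plus a random multiple of the
difference to a neighbour) is documented history here: the operative
update is the binary keep/re-draw rule above.

## Classifiers, evaluation, statistics

Classifier training is delegated to standard libraries (`rpart`,
`randomForest`, `class`, `e1071`); the package owns the named
configurations, folding, metrics and statistics. The twelve
configurations: decision trees pruned to at most 100/20/3 splits
(grown with cp = 0, pruned back via the complexity table — rpart has
no direct maximum-splits control); a 100-tree random forest; kNN with
1/3/20 neighbours (Euclidean) plus a cosine variant (k = 10, not
stated in the source method; cosine ranking implemented as Euclidean
kNN on L2-normalized rows); SVMs with linear, quadratic, cubic
(`coef0 = 1`, the inhomogeneous form — a pure even-power kernel is
sign-invariant and cannot learn a mean shift) and Gaussian-RBF kernels.

*fast* is the positive class throughout. Folds are stratified (the
balanced design makes that the faithful reading of "5-fold").
Features are z-scored per column, fitted on training folds only, for
the distance- and margin-based learners; trees are left unscaled.
Confusion matrices pool held-out predictions across folds (per-fold
averaging differs only in weighting when folds are unequal). ROC
curves sweep thresholds over pooled held-out scores; the median-curve
variant interpolates repeated runs on a common grid.

The ABC vs no-ABC comparison is a two-sided t-test on per-repeat
accuracies (5 repeats with derived fold seeds). The reference results
print df = 4 for two groups of five — the *paired* formula — while
calling the test independent-samples; both modes are provided and
paired is the default, matching the printed degrees of freedom. The
repeats share fold seeds between the two conditions, which also makes
pairing the statistically natural choice.

## Synthetic data: what it emulates, and what it does not

`gen_rt()` draws RT(t, q) = base + Gaussian noise and subtracts a
fixed effect from Q4 at and after the learning onset — the premise the
TRT rule needs. `gen_epochs()` builds each channel as a sum of
unit-variance band components; informative (channel, band) components
switch their AR(1) coefficient from `ar_base` (0.2) to
`ar_base + complexity_gap` (default gap 0.6) for fast-class trials.
Variance is equalized across classes, so class separation lives where
MSE looks — in temporal structure, not amplitude. `gen_feature_table()`
plants the same kind of structure directly in feature space (a
baseline profile decreasing with scale, informative columns shifted
down by `separation` SDs for the fast class — more regular signals
have lower entropy), for tests of the selection and evaluation stages
that do not need the signal-processing front end.

Defaults describe the emulated study: 100 trials of four 3 s questions
at 1000 Hz, nine frontal channels, learning onset at trial 50, RT base
1.5 s with 0.1 s noise and a 0.5 s Q4 effect, separation 1 SD.

Honest limitations of the emulation: components are stationary AR
processes, with none of the nonstationarity, artifacts, volume
conduction or cross-channel correlation of real EEG; the planted
complexity difference is channel-clean. A gap planted *inside* a
narrow band is only weakly visible in that band's MSE (the oscillation
dominates the entropy), so end-to-end recovery tests plant in
broadband components of specific channels. Passing tests therefore
show the pipeline's machinery is correct and sensitive to planted
complexity differences at realistic sizes — not that real EEG carries
such differences.

## Problem sizes and numerical choices in the tests

The suite runs the full pipeline at desk scale: 44 trials, 3 channels,
2 bands, 200 Hz, 3 s epochs, 4 scales (five seeds); ABC recovery on
planted tables at the study's balanced class size (175 per class, 12
features, 3 informative, 30 iterations, 20 seeds); the ABC-vs-no-ABC
comparison on 10 experiments of 120 rows each. The transparent
count-the-ones fitness checks the optimizer against an exhaustively
known optimum at d = 8. Determinism is asserted at the run level:
same seed, same trace, byte-identical generated data.

Degenerate inputs are contracts, not surprises: ragged CSVs, events
beyond the recording, epochs too short for the requested scale,
all-zero selections, one-class tables, sub-k class counts and
zero-variance windows all raise named errors or documented fallbacks
(`bound = urt`, uniform roulette on all-zero fitness).
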