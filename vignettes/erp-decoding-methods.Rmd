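---
title: "Methods: time-resolved decoding of simulated lifespan ERP data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved decoding of simulated lifespan ERP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpdecode)
```

## What the package computes

`erpdecode` implements a single-trial multivariate decoding pipeline for
epoched EEG from a flanker-style selective-attention task, across six age
groups spanning childhood to old age. Two complementary questions are asked
of the same data:

1. **Group decoding** — can a classifier tell which age group a single
   trial came from? Trials of all participants are pooled, spatially
   filtered, and classified with participant-wise stratified ten-fold
   cross-validation, so test participants are never seen during training.
2. **Stimulus decoding** — within each participant, can congruent be told
   from incongruent flanker trials, and *when* is that information present?
   A sliding-window classifier traces an AUC-over-time trajectory whose
   peak and peak latency are then compared between groups.

Because raw recordings from such studies are rarely redistributable, the
package carries a parametric ERP simulator as a first-class module; every
downstream stage is exercised end to end on data with known ground truth.

## The generative model

Each trial of a simulated participant is

$$X(t) \;=\; \sum_c a_c \, e^{-(t-\ell_c)^2 / 2 w_c^2}\, \mathbf{m}_c \;+\;
\varepsilon(t),$$

where component $c$ (P1, N1, N2, P3, or custom) has signed peak amplitude
$a_c$ (µV), peak latency $\ell_c$ (ms), Gaussian envelope width $w_c$ (ms),
and a fixed unit-norm spatial map $\mathbf{m}_c$ built as a smooth Gaussian
bump over an approximate 2-d projection of the BioSemi 32-channel 10–20
montage (P1/N1 occipital, N2 fronto-central, P3 parietal). $a_c$ and
$\ell_c$ are drawn once per participant (between-participant variability);
on incongruent trials a condition delta is added to the amplitude (larger,
i.e. more negative, N2) and/or the latency (delayed P3) — this is the only
source of stimulus information, matching the additive evoked-response
assumption that underlies xDAWN filtering. $\varepsilon$ is $1/f$ noise,
synthesised per channel in the frequency domain and rescaled to an exact
per-channel standard deviation.

Default study conditions follow the published design: six groups of
46/39/21/25/40/38 participants; per-participant correct-trial counts drawn
from each group's truncated normal (e.g. children incongruent: mean 70.91,
sd 15.30, range 36–98); 32 channels at 256 Hz; epochs covering −100 to
800 ms around stimulus onset. Age effects default to a u-shaped pattern:
children and the two oldest groups receive +80 ms latency and ×1.4
amplitude on P1/N1 and a +150 ms shift of the condition-discriminative
N2→P3 window. Reaction times are lognormal with group-specific means
(children and older groups slower, incongruent slower than congruent) and
error probabilities of 4 % (congruent) and 8 % (incongruent), so the
quality-control stages have realistic work to do. All of this is
configuration, not constants.

What the simulator does **not** emulate: ocular or muscle artifacts,
volume-conducted correlated noise, non-stationarity across the session,
or overlapping responses from neighbouring trials. Passing tests therefore
demonstrate correctness of the pipeline's algorithms on data satisfying
the additive-ERP assumption, not robustness to every pathology of real
recordings.

Seeding: one master seed; participant seeds are derived deterministically
from (master, group index, participant index), so a dataset is reproducible
participant by participant.

## Preprocessing conventions

* **Band-pass** (default 1–40 Hz): Hamming-windowed linear-phase FIR with
  transition bandwidths `min(max(0.25·f, 2), f)` below and
  `min(max(0.25·f, 2), Nyquist − f)` above, length `3.3/transition`
  seconds, applied once with group-delay compensation (zero net phase) and
  constant edge padding. A 1 Hz high-pass implies an ~845-tap kernel at
  256 Hz; on epochs shorter than the kernel the filter is truncated to the
  epoch length with a warning — low-frequency response near the edges is
  then only approximate. No separate baseline correction is applied; the
  high-pass is relied on.
* **Resampling** is Fourier-domain (spectrum truncation), with the new
  sample count `round(n · target/current)`.
* **Epoch grid**: −100 ms is not on the 256 Hz grid, so cropping snaps the
  lower edge outward to the previous sample and keeps samples up to the
  upper edge: samples −26…204 relative to onset, i.e. 231 samples spanning
  −101.56…796.88 ms. Displayed times are rounded; computations use grid
  times.
* **Trial selection**: correct responses with reaction times in
  [100, 1200] ms (inclusive at both ends — the verbal rule "between" is
  ambiguous and inclusivity is this package's convention); only congruent
  and incongruent conditions are analysed. Participants with fewer than 35
  correct trials in either condition (strict `<`) are excluded *after* the
  response-time filter, since that filter defines what a correct trial is.
  "Poor data quality" exclusions are a manual flag, not an automatic
  detector.

## xDAWN spatial filtering

For class $c$ with class-average evoked $E_c$ (channels × samples), signal
covariance $S_c = E_c E_c^\top / n_s$ and total covariance
$T = \tfrac1n \sum_i X_i X_i^\top / n_s$, the filters maximise the
signal-to-signal-plus-noise Rayleigh quotient
$w^\top S_c w \,/\, w^\top T w$. We use the epoched-data variant
(class-average evoked rather than the original continuous-data least
squares with a Toeplitz design), which optimises the same objective when
stimulus responses do not overlap — true at this paradigm's inter-trial
intervals. Numerics: $T$ gets a diagonal shrinkage of
$10^{-10}\,\mathrm{tr}(T)/n_{ch}$, is Cholesky-whitened, and a symmetric
eigendecomposition is done in whitened space; ties are broken by stable
eigenvalue order with the first non-zero filter coefficient made positive.
"Five spatial filters" is interpreted as five components **per class**
(the common toolbox convention), so binary problems yield 10 virtual
channels and six-class problems 30. Filters are always fitted on training
folds only.

## Decoding

The classifier is a radial-basis SVM with cost 1 and kernel width
$1/(d\,\widehat{\mathrm{var}})$ on features standardised by training-set
mean and sd — the de-facto defaults of the toolchain this style of analysis
is usually built on. Hyperparameters are deliberately not tuned.

* *Group decoding*: participant-wise stratified ten-fold CV; training
  trials are randomly subsampled to the minority class per fold; the
  whole-trial model flattens virtual channels × all samples; the confusion
  matrix is aggregated over folds (accuracy = trace/total).
* *Stimulus decoding*: ten stratified shuffle splits at a held-out
  fraction of 0.20 (the published mean train/test sizes of 113.6/28.9
  trials imply ≈ 0.203); xDAWN is fitted once per split on full-length
  epochs and windows are cut from the filtered signal (refitting per
  window would also be defensible; fitting once matches "filters trained
  on the preprocessed segments" and costs a factor of ~200 less); each
  20-sample window (19 overlap) yields one AUC per split; a window's
  timestamp is its centre sample's time. AUC is the midrank Mann–Whitney
  statistic.

## Chance levels and group statistics

Large-sample group decoding uses the analytic binomial threshold: the
smallest $k$ with $F_{\mathrm{Binom}(n,1/c)}(k) \ge 1-\alpha$, divided by
$n$, with $n$ the full per-fold trial count (training + test ≈ 24 520);
that convention reproduces the printed two-decimal chance level of 0.17,
whereas using the test count alone would give 0.18. Small-sample
within-participant decoding uses a label-permutation null: labels are
shuffled across trials *before* splitting, the entire pipeline is re-run,
and the maximum over windows of the fold-mean AUC is recorded — the
statistic the threshold is later applied to (peak performance). Nulls are
pooled across participants and the threshold is the nearest-rank 95th
percentile. The pooled-null composition (all permutations of all
participants) is this package's choice; per-participant maxima are pooled
rather than per-window values because peak AUC is the tested quantity.

Peak metrics (max fold-mean AUC and its time, earliest window on ties —
deterministic and conservative toward earlier processes) feed the group
stage: Shapiro–Wilk per group at α = 0.05 gates between one-way ANOVA with
all-pairs Welch t tests and Kruskal–Wallis with Dunn's large-sample z
tests (tie-corrected); post-hoc p values are Benjamini–Hochberg adjusted
within each omnibus family and reported only when the omnibus test is
significant.

## Numerical and testing choices

Desk-scale test problems use 16 channels at 64 Hz (59-sample epochs),
~100 trials per participant, 4–10 splits and 100 permutations; these sizes
make the calibration suites statistically meaningful while keeping a full
run of the package's checks in the minutes range. The type-I calibration
compares the fraction of null participants whose peak AUC clears the
permutation threshold against the exact binomial 95 % band around 0.05,
and six-group null decoding against the band around 1/6. The latency
recovery suite injects a −3 µV condition effect at 200 ms (adult groups)
versus 400 ms (children/oldest groups) over 3 µV 1/f noise and requires
group-median peak times within ±40 ms plus FDR-significant post-hoc
separation of shifted from unshifted groups.

Degenerate inputs are handled explicitly: zero-noise configurations are
exactly reproducible against the closed-form component sum; zero-variance
groups route to the nonparametric branch; empty crops, single-class
training sets, under-sampled conditions, and QC that excludes everyone all
raise informative errors.

## Known limitations

* The FIR response is compromised on epochs shorter than the designed
  kernel (inevitable for a 1 Hz high-pass on 0.9 s segments); filtering
  continuous data before epoching, as acquisition pipelines do, avoids
  this but is out of scope here.
* The SVM backend (libsvm) is deterministic for fixed inputs but its
  decision values are not invariant to trial order at exact floating-point
  resolution; seeds fix all orderings.
* Generalized eigenvalues are only guaranteed in [0, 1] when every class's
  evoked power is contained in the total covariance (e.g. balanced designs
  with comparable class responses); strongly asymmetric designs can exceed
  1 without being wrong.
* The group-level permutation threshold assumes exchangeability of
  condition labels within participant; it does not correct for multiple
  comparisons across time windows beyond using the peak statistic.
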