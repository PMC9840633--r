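---
title: "Dendrographic hologram signatures: model, conventions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dendrographic hologram signatures: model, conventions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhsig)
```

## 1. The model

The package treats a multichannel EEG recording not as a collection of
waveforms but as a population of **events** — one event per electrode per
one-second window — and characterizes the *hierarchy of relations* among
events. The pipeline is:

1. **Segmentation.** A recording of `C` channels at `fs` Hz is cut into
   consecutive non-overlapping 1-s windows; each (electrode, window) pair
   becomes one event vector of `fs` samples. For the reference regime
   (19 channels, 500 Hz, 500 s) this yields 9500 events and
   9500·9499/2 = 45,120,250 pairwise distances.
2. **Ward dendrogram.** Events are agglomerated by Ward's minimum-variance
   criterion on Euclidean distances into a single binary tree.
3. **2-adic coding.** Each leaf's root-to-leaf path becomes a binary string
   `a_0 … a_k` with value `V = Σ a_j 2^j`. The tree hierarchy then induces
   the 2-adic ultrametric: two leaves are close exactly when their common
   root-branch is long.
4. **Signatures.** PUDHS counts branches with `V` below
   `T = 2^(max_ball − z)` where `max_ball = ⌊log2 max V⌋`; PBDHS does the
   same per short block dendrogram under two thresholds and compresses the
   count histograms into one scalar.

The underlying assumption is that group differences express themselves in
the *topology* of the event dendrogram — how finely the event population
fragments into sub-dendrograms — rather than in signal amplitude. Branch
heights never enter the signatures; only the merge structure does.

## 2. Frozen encoding conventions

Two choices in the 2-adic coding are not forced by the mathematics, change
individual `V` values, and are therefore frozen as part of the signature's
definition:

* **Digit orientation.** `a_0` (the `2^0` place) is the digit chosen at
  the *root* split and `a_k` the digit at the leaf's final split. With the
  root at the lowest-order position, `|V_a − V_b|` in the 2-adic norm is
  small precisely when the common root-branch is long, which is the stated
  semantics of the tree metric. The digit count `k+1` is per-leaf, since
  Ward trees are unbalanced.
* **Child labeling.** At every internal node, the child subtree containing
  the smallest leaf id takes digit 0. Any consistent rule is admissible;
  this one is deterministic under row permutation modulo tree isomorphism
  and is what the test-suite oracles implement independently.

Consequences worth knowing: every tree has exactly one all-zeros leaf
(`V = 0`). Its 2-adic ball `⌊log2 V⌋` is undefined; the package treats it
as `−Inf`, i.e. *below every threshold*, so it always counts toward
PUDHS/E. The maximal ball of a tree with `n ≥ 2` leaves is always `≥ 0`.

## 3. Exact arithmetic without big integers

For a 9500-leaf tree, leaf depths reach hundreds, so `V` can far exceed
the 53-bit exact range of doubles, and no arbitrary-precision integer
package is assumed. The package never forms large `V` numerically: every
signature comparison has the form `V < 2^e`, which holds **iff** the
highest set bit of `V` is below `e` — i.e. iff `ball(V) < e`. Balls are
integers read directly off the digit strings, so all thresholds, counts
and maxima are exact at any depth. The numeric `value` field of a coded
tree is populated only when `V < 2^53` (NA otherwise); `value_bits` always
carries the exact binary representation for export.

## 4. Ward implementation and tie-breaking

Ward linkage runs as a nearest-neighbor-chain in C++ on the condensed
squared-distance vector (Lance–Williams update), with heights reported on
the distance scale — the `ward.D2` convention. Heights are monotone along
the merge sequence (Ward is reducible), and the test suite checks exact
partition agreement with `stats::hclust(method = "ward.D2")` on random
inputs, keeping library and implementation as independent routes.

Equal-cost merges are resolved by *smallest cluster index wins* within the
nearest-neighbor scan, and the final stable sort by height preserves merge
order among ties. Real EEG essentially never ties; synthetic fixtures can,
and a deterministic rule keeps cohorts reproducible. Since heights do not
enter the signatures, the tie rule can only matter through topology, and
only for exactly tied merge costs.

Distances are computed block-wise through BLAS (`|x_i|² + |x_j|² −
2 x_i·x_j`), materializing nothing larger than the condensed vector plus an
O(block × n) temporary — the full 9500-event regime fits comfortably in
desk memory and runs in about a minute.

## 5. Tunable parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `window_s` | event length (s) | 1 | fixed by the method's regime |
| `total_s` | analyzed span (s) | all whole windows | 500 in the reference regime |
| `offset_s` | start offset (s) | 0 | for segment-shift robustness checks |
| `z` | PUDHS threshold exponent | 4 | natural number, scanned 1–8 by `pudhs_scan()` |
| `block_windows` | windows per block | 10 | 1/3/5/10 give 19/57/95/190-leaf blocks |
| `z1`, `z2` | intra-/inter-block exponents | searched 1–8 | 64 combinations |
| `h` | sampled bin centres | 10 | uniform, without replacement from 1..m |
| `n_reps` | draws per (z1, z2) | 10,000 | raise toward 1e6 for exhaustive searches |
| `hp_hz` | high-pass cutoff (Hz) | 1 | zero-phase, Butterworth-magnitude, order 4 |
| `notch_hz` | mains notch (Hz) | 50 | Gaussian dip, Q = 30; needs `fs > 2·notch` |

`z` is one global value applied to every subject of a cohort — thresholds
are *personal* only through each subject's own `max_ball`. PUDHS is
non-increasing in `z` (the threshold halves per step). For the block
search, each `(p, p1)` draw is applied to **all** subjects of a repetition;
without that, per-subject PBDHS values would not be comparable in the AUC
objective.

A documented discrepancy: in the source regime the construction bounds
PUDHS by the 9500 available branches, while reported group means slightly
exceed that bound; the package enforces `PUDHS ≤ n_leaves` and does not
emulate the excess. Likewise a 3-window block decomposition of 500 windows
gives `⌊500/3⌋ = 166` blocks (trailing partial block dropped), although
167 appears once in the source's text.

## 6. Preprocessing choices

Only the cutoff frequencies of the filters are inherited from the method's
regime (1 Hz high-pass, 50 Hz notch); the filter family is an
implementation choice. With no DSP package assumed, both filters are
applied as **zero-phase frequency-domain multiplications**: a
Butterworth-magnitude high-pass (order 4) and a Gaussian notch
(bandwidth `notch_hz / Q`, Q = 30). Zero phase holds by construction
(real, symmetric response). The suite verifies >95 % RMS attenuation of a
pure 50 Hz tone and removal of DC to below 1e-6. Recordings at other
sampling rates are resampled to 500 Hz by the pipeline (Fourier method)
unless resampling is disabled, in which case a mismatch is an error.
Non-finite samples after loading are a hard error; the package does not
impute.

## 7. What the synthetic generator does and does not emulate

`generate_recording()` builds each channel as a weighted sum of
band-limited filtered-noise oscillators (the five canonical bands), where
each band's oscillation splits into a component **shared across channels**
(weight `√coupling`) and an independent component (weight `√(1−coupling)`),
plus a slow `< 0.1 Hz` drift scaled by `nonstationarity` and white sensor
noise. The oscillatory part is scaled to a 50 µV SD, a typical resting
scalp amplitude. Defaults follow the acquisition regime the method
targets: 19 channels, 500 Hz, 500 s, alpha-dominant band weights.

This gives precise control over the two properties the signatures respond
to — inter-channel coupling and slow nonstationarity — and satisfies the
checked invariants (spectral concentration, coupling-monotone correlation,
bit-determinism). It is **not** physiological EEG: no dipole geometry, no
1/f background, no artifacts (blinks, EMG), no state transitions. A green
synthetic test therefore establishes that the *machinery* is correct and
that the signature responds to relational structure as designed; it says
nothing about clinical separability, which depends on real cohort data
outside this package's test surface.

Cohort generation derives per-subject seeds deterministically from
`(master seed, group index, subject index)`, so cohorts are reproducible
subject-by-subject regardless of generation order.

## 8. Numerical and degenerate-input policy

* Threshold comparisons: strict (`V < T`), in exact ball arithmetic
  (section 3). `T` itself is reported both as `2^exponent` (possibly
  overflowing to `Inf` for display) and as the exact exponent.
* `z ≥ max_ball + 1` makes `T ≤ 1` so only the `V = 0` branch counts:
  allowed with a warning, not an error.
* Blocks with `E = 0` fall outside the 1..m histogram support (bins start
  at 1) and are excluded from `F`; their count is reported
  (`n_zero_E`) so conservation `ΣF + #zero = n` remains checkable.
* A single event cannot form a tree: two or more events are required
  everywhere; non-finite distances abort tree construction with position
  information.
* ROC orientation is not forced above 0.5; the raw AUC and a flipped
  convenience value are both reported. AUC p-values use the large-sample
  Mann–Whitney normal approximation with tie correction — a package
  choice, documented rather than inherited.
* The random-grouping null reports the raw SD of the AUC distribution;
  plotting conventions that show `±3·SD` should multiply, not the package.

## 9. Scale of the shipped checks

The full 19 × 500 regime runs once in the acceptance tests (structural
counts, about a minute); all other checks run on scaled-down cohorts
(tens of seconds of synthetic signal, 125–250 Hz) chosen so the entire
suite completes in minutes. The discrimination regression (coupling 0.9
vs 0.1, n = 10 per group) uses 60-s recordings; its observed AUC (0.955)
is frozen in the test as a regression guard, and the rank-sum separation
it asserts was verified to strengthen, not weaken, with recording length.
The acceptance script's 166-subject null-calibration target is likewise
computed at 60-s scale; the statistic it reports destroys group labels
before measuring, so recording length cannot bias its expectation.

## 10. Known limitations

* EDF support is minimal (16-bit, uniform rate across retained channels,
  one-second records on write); EDF+ annotation signals are dropped by
  label blacklist, not parsed.
* The PBDHS search reports in-sample summed AUC; no multiple-testing
  correction or cross-validation is applied (faithful to the method's
  definition — treat the maximized AUC as descriptive, not inferential).
* `search_pbdhs` at the exhaustive scale (64 combinations × 1e6 reps) is
  hours of compute; the default 10,000 reps is a desk-scale setting.
* The 2-adic values depend on the frozen child-labeling convention;
  signatures computed under a different convention are not comparable
  across implementations, only within one.
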