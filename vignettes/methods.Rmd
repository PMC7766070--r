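---
title: "Estimating conduction velocity and directionality of uterine EHG waves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating conduction velocity and directionality of uterine EHG waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehgcv)
```

## The measurement problem

Uterine electrical activity reaches the abdominal surface as travelling
electrohysterogram (EHG) waves. With four electrodes at the corners of a
square of side $d$ (7 cm in the supported recordings) wired into bipolar
derivations — $S_1 = E_2 - E_1$ across the top pair, $S_2 = E_2 - E_3$ down
the left pair, $S_3 = E_4 - E_3$ across the bottom pair — the lag between the
upper and lower signals carries the vertical travel time of a wavefront, and
the lag between the left and right signals its horizontal travel time. The
fourth derivation is not recorded in the supported dataset and follows from
the montage algebra as $S_4 = E_4 - E_1 = S_1 - S_2 + S_3$; `derive_s4()`
implements exactly this identity, and the generator's unipolar channels let a
test verify it against direct potential differencing. For consistent
correlation polarity, $S_3$ and $S_4$ are flipped by $-1$ (`orient_signals()`),
and the flip is recorded so it cannot be applied twice.

Under a planar-wave assumption, piecewise linear over each short analysis
step, the two transitional times $t_V$ and $t_H$ determine the
conduction-velocity amplitude and the incidence angle measured from the
vertical axis:

$$
\mathrm{CV} = \frac{d}{\sqrt{t_V^2 + t_H^2}}, \qquad
\varphi = \operatorname{atan2}(t_H,\, t_V).
$$

Angles map onto four half-open compass sectors:
$[-45^\circ, 45^\circ)$ south (vertical), $[45^\circ, 135^\circ)$ east
(horizontal), $[135^\circ, 180^\circ) \cup [-180^\circ, -135^\circ)$ north,
$[-135^\circ, -45^\circ)$ west. The two-quadrant arctangent of $t_H/t_V$
cannot reach all four sectors, so the implementation resolves the quadrant
from the signs of $(t_V, t_H)$.

## Short-time cross-correlation

The estimator (`ehg_track()`) tiles the record into correlation intervals of
`d_ci` = 0.5 s, the first centred `w_c/2` = 2.5 s into the record. At each
centre a 5 s window is cut from the pair $(S_1, S_3)$ and from $(S_2, S_4)$,
each window min–max normalized to $[0, 1]$
(`window_normalize()`; a constant window is degenerate and yields "no
propagation"), and the similarity shift is the integer lag
$m \in [-d_{ss} f_s, +d_{ss} f_s]$ (±20 samples at 20 Hz) maximizing the
cross-correlation $C(m) = \sum_n x(n)\, y(n-m)$. Transitional times follow as
$t = -s/f_s$; two cases are set to $\mathrm{CV} = 0$ with undefined angle:
both shifts zero (no propagation), and $\mathrm{CV} > 30$ cm/s
(non-physiological outlier — the implied transitional times are a sample or
two, indistinguishable from method failure).

Numerical choices worth stating explicitly:

* **Overlap scaling.** Within a finite window only $N - |m|$ products exist
  at lag $m$. On non-negative normalized windows (mean ≈ 0.5) the raw
  truncated sum acquires an overlap term proportional to $N - |m|$ that
  dominates the correlation and drags the argmax toward zero lag whatever the
  signals do; a noise-free synthetic wave at $\varphi^* = 30^\circ$,
  $\mathrm{CV}^* = 10$ cm/s demonstrably loses its true peak to lag 0 this
  way. `similarity_shift()` therefore maximizes the unbiased finite-sample
  estimate $C(m)/(N - |m|)$, the standard finite-window realization of the
  infinite-sum definition. With it the noise-free recovery sweep is exact up
  to lag quantization.
* **Tie-breaking.** Ties at the maximum go to the smallest $|m|$, then to the
  negative lag, biasing ambiguous windows toward "no propagation" rather than
  toward spurious fast waves.
* **No mean removal.** Correlation is computed on the $[0,1]$ windows as the
  normalization prescribes, without Pearson centring; `window_normalize()` is
  applied per window and per signal.
* **Edges.** Windows that would overrun the record are omitted rather than
  zero-padded (padding biases shifts toward 0). A 30-minute record therefore
  yields exactly $(1800 - 5)/0.5 + 1 = 3591$ estimates.
* **Sign bookkeeping.** The summation convention, the $-1$ in $t = -s/f_s$,
  the orientation flip of $S_3/S_4$ and the electrode layout interact; the
  package fixes all signs by one end-to-end anchor, enforced in tests against
  the synthetic generator: a wave travelling upward produces a positive
  vertical shift, and the closed forms ($t_V = 0.7$ s, $t_H = 0$ →
  CV = 10 cm/s, $\varphi = 0^\circ$, south) hold exactly.

The searched lag range imposes a geometric observability constraint: with
$d = 7$ cm and $d_{ss} = 1$ s, an axis-aligned wave slower than 7 cm/s has a
true lag beyond the searched ±20 samples and cannot be measured (on the
diagonal the floor is $d/(\sqrt 2\, d_{ss}) \approx 4.95$ cm/s). Recovery
tests therefore sweep the feasible grid
$|d \cos\varphi|, |d \sin\varphi| \le \mathrm{CV}\, d_{ss}$.

## Frequency bands and filtering

Analysis runs per band: B0′ (0.3–1.0 Hz, contraction-related activity), Bb
(0.3–4.0 Hz, broad burst content), and B1 (1.0–2.2), B2 (2.2–3.5), B3
(3.5–5.0 Hz), the region above 1 Hz where the maternal heart rate and its
harmonics influence the uterus. The fixed pipeline order is: wide-band filter
(0.08–5.0 Hz) → derive $S_4$ → per-band filter all four signals → orient.
Filtering is linear, so deriving $S_4$ before or after the per-band filter is
equivalent; a test asserts the equivalence to $10^{-9}$ rather than assuming
it.

Filters are fourth-order Butterworth band-passes in the `butter(4, c(low,
high))` convention (eight poles, four per edge — the bidirectional roll-off
of 160 dB/decade pins this reading down) applied forward–backward for zero
phase. Edge transients are controlled with odd-reflection padding of
$3(\mathrm{order}+1)$ samples and steady-state initial conditions at the
padded signal's first value; without the steady-state initialization a
constant input leaves visible stop-band leakage at the edges. The analog
3-pole 0.0–5.0 Hz acquisition filter of the recorder is not simulated:
it is a property of the hardware, not of the method, and synthetic signals
are treated as already acquisition-filtered.

## Per-interval features and sample entropy

For an annotated interval (half-open `[start, end)` in 0-based samples; an
estimate belongs to the interval iff its centre sample lies inside), the
propagation features are: $P_V = 100 N_V/N$ and $P_H = 100 N_H/N$, where $N$
counts *all* correlation intervals including those without propagation and
$N_V, N_H$ only the directed ones; their ratio $RP_{VH}$; the mean
conduction velocities $\bar V_V, \bar V_H$ over the $\mathrm{CV} \neq 0$
members and their ratio $RV_{VH}$; and the same percentages and means per
sector. Ratios and means over empty sets are flagged undefined (`NA`) and
excluded pairwise downstream — never imputed. Two identities are enforced by
tests on every generated row: $P_S + P_N + P_E + P_W = P_V + P_H$ and
$N_V \bar V_V + N_H \bar V_H = \sum \mathrm{CV}$.

Sample entropy uses template length $m = 3$ and margin $r = 0.15$, with $r$
interpreted as a fraction of the analysed segment's standard deviation (the
near-universal convention of the SampEn literature; an absolute-$r$ mode is
available). Matching is Chebyshev with self-matches excluded and both counts
taken over templates starting at $1..N-m$;
$\mathrm{SampEn} = -\ln(A/B)$, undefined when either count is zero. It is
computed on the band-filtered $S_2$ and $S_3$ segments of each interval,
without decimation (none is part of the protocol; a config hook could add
it). The fast implementation is required by tests to equal brute-force
pairwise counting exactly.

## Classification protocol

Group separation of individual features uses the two-sample pooled-variance
t-test. Classification is quadratic discriminant analysis — per-class mean
and covariance, equal priors (classes are balanced by construction),
covariance regularized by $\varepsilon I$
($\varepsilon = 10^{-6}\,\mathrm{tr}(\Sigma)/p$) only when singular —
evaluated by stratified 10-fold cross-validation repeated 30 times with
distinct fold shuffles; repetition seeds are fixed offsets from a master
seed, so every report is bit-reproducible. Sensitivity, specificity and
accuracy come from pooled per-repetition confusion counts (preterm is the
positive class); AUC is the rank statistic of the continuous discriminant
score. Class imbalance (47 preterm vs 53 term intervals) is handled by SMOTE
with $k = 5$ neighbours, raising the minority to 53.

SMOTE placement is a genuine fork: the published protocol balances the whole
interval set before cross-validation, which leaks synthetic neighbours of
test points into training folds and flatters absolute accuracy. Both modes
are first-class here — `smote_mode = "whole"` (default, matching the
protocol) and `"folds"` (SMOTE inside training folds only, for honest
generalization estimates) — and reports name the mode used. A guard test
requires label-shuffled cohorts to classify at chance (50 ± 10%) in *both*
modes.

## The synthetic generator

`simulate_record()` builds records in which every downstream number has a
known ground truth. Each unipolar potential is a gain-scaled, delayed copy of
a common burst waveform, $E_i(t) = g_i \sum_w w(t - \tau_i)$ + white noise,
with $\tau_i$ the projection of the electrode position onto the unit
propagation vector divided by the true speed; bipolar channels are derived
exactly from the potentials, so the montage identity holds by construction
and the estimator sees precisely the geometry it assumes.

Two generator choices deserve their rationale:

* **Gain heterogeneity** (defaults 0.99, 1.02, 1.01, 0.98 for $E_1..E_4$).
  A perfectly planar wave travelling exactly along an axis reaches both
  electrodes of the perpendicular pair simultaneously, so their difference
  cancels identically and the corresponding lag would be unobservable — a
  measure-zero degeneracy that real recordings never exhibit because
  electrode–skin coupling differs between sites. The small gain spread
  models that coupling difference; it leaves every ground-truth delay
  untouched. The gains are chosen with matched ratios
  ($g_2/g_1 \approx g_3/g_4$, $g_2/g_3 \approx g_1/g_4$) so paired windows
  keep near-identical shapes.
* **Broadband bursts.** The default waveform is a Gaussian-windowed sum of
  several spectral lines inside the analysed band. A single carrier is
  near-periodic at the relevant delays (0.7 s at 1.5 Hz is 1.05 cycles), so
  the correlation peak aliases; real EHG is broadband within each band.

What the generator does *not* emulate: curved wavefronts, anatomically
realistic sources, overlapping waves, ongoing background activity in quiet
spans, or nonstationary noise. Synthetic "dummy" annotations cover
noise-only gaps, so — unlike in real records, where non-contraction segments
carry maternal-heart-related activity — synthetic dummy intervals contain no
class signal; classification demonstrations therefore use contraction
intervals or the feature-level cohort generator. Consequently, passing tests
certify the estimator, feature algebra and protocol mechanics, not clinical
performance on real recordings.

`simulate_feature_cohort()` draws per-interval feature vectors directly:
class means and spreads for $P_V$ and $P_H$ follow the published
band-B2 dummy-interval statistics (preterm 36.5/45.4%, term 40.6/38.2%,
with a mild negative correlation since the percentages compete for the same
intervals), and the $\mathrm{SE}_{S2}$ distributions (reported only
graphically in the source study) are a synthetic stand-in with the published
direction of effect, term 1.30 ± 0.25 vs preterm 0.95 ± 0.25. These defaults
are fixed study conditions, not tuning knobs.

## Problem sizes and reproducibility

The test suite and the acceptance script run on deliberately compact inputs
chosen once: 30 s single-wave records for the recovery sweep (about 50
feasible cv × φ combinations), 120 s two-wave records for feature identities,
series of up to 2000 samples for sample entropy, and the 47 + 53 cohort with
10 × 30 cross-validation for the protocol. `scripts/acceptance.R --seed S
--out f.json` recomputes every reported quantity from scratch; all
randomness derives from the one seed, and identical configurations reproduce
byte-identical artifacts (the pipeline tags every output file with a
configuration hash, so changed parameters can never silently overwrite old
results).

## Known limitations

* Lag quantization at 20 Hz limits velocity resolution (no sub-sample
  interpolation, by scope); the relative error bound per axis is
  $f_s^{-1}(|\cos\varphi| + |\sin\varphi|)/d$ in $1/\mathrm{CV}$.
* Axis-aligned waves slower than $d/d_{ss}$ = 7 cm/s are outside the
  searchable lag range — a constraint of the window geometry, not a bug.
* The WFDB reader covers single-segment format-16 records and MIT-format
  annotations with paired begin/end aux marks, which is what the supported
  dataset uses; the annotation symbol table is configurable because symbol
  schemes are a dataset convention.
* Whole-set SMOTE (the published protocol) produces optimistic absolute
  accuracies; use `smote_mode = "folds"` when an unbiased estimate matters.
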