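# ehgcv

Conduction velocity and directionality of uterine electrical activity from
surface EHG records.

## What it does, and for whom

The electrohysterogram (EHG) records uterine electrical activity from the
maternal abdomen. Waves of that activity travel across the abdominal surface,
and their speed and direction carry information about the state of the
uterus during pregnancy — including markers that help distinguish pregnancies
ending in preterm birth from term ones. `ehgcv` is for biomedical-signal
researchers working with multichannel EHG recordings (such as the public
term/preterm dataset with tocogram distributed by PhysioNet: 20 Hz, three
bipolar signals, human-annotated contraction and non-contraction "dummy"
intervals) who want a tested, reproducible implementation of the
short-time cross-correlation approach to EHG wave velocity, the derived
propagation features, and the accompanying classification protocol.

## The method in brief

Four electrodes form a square of side *d* = 7 cm; bipolar derivations are
S1 = E2−E1 (top), S2 = E2−E3 (left), S3 = E4−E3 (bottom), and the missing
right derivation follows from the montage identity S4 = S1 − S2 + S3. After
zero-phase Butterworth band-pass filtering (bands B0′ 0.3–1.0, Bb 0.3–4.0,
B1 1.0–2.2, B2 2.2–3.5, B3 3.5–5.0 Hz), a 5 s correlation window slides in
0.5 s steps; in each window the lags maximizing the cross-correlation of the
min–max-normalized pairs (S1, S3) and (S2, S4) over ±1 s give the vertical
and horizontal similarity shifts *s_V*, *s_H*. With transitional times
*t* = −*s*/*f_s*, a planar wave has

    CV = d / sqrt(t_V^2 + t_H^2),    phi = atan2(t_H, t_V),

an amplitude capped at 30 cm/s (faster estimates are non-physiological
outliers, set to "no propagation") and an incidence angle mapped to the
south/east/north/west sectors. Per annotated interval the package computes
the direction percentages P_V, P_H, their ratio RP_VH, mean velocities
V̄_V, V̄_H, their ratio RV_VH, sector statistics, and the sample entropy
(m = 3, r = 0.15) of the band-filtered S2 and S3 segments. Preterm-vs-term
classification uses SMOTE balancing (47 → 53), quadratic discriminant
analysis, and stratified 10-fold cross-validation with 30 repetitions,
reporting Se/Sp/CA/AUC.

A synthetic planar-wave generator with exact ground truth (unipolar
potentials, bipolar identities, known speed and angle) makes the entire
stack verifiable without downloading any data.

## Worked example

Simulate a wave crossing the array at 10 cm/s, 30° from vertical, track it,
and recover the ground truth:

```r
library(ehgcv)
w   <- wave_spec(cv = 10, phi = 30, onset_s = 15)
rec <- simulate_record(w, duration_s = 30, noise_sd = 1, seed = 42)
tr  <- ehg_track(rec, band = "B1")
summary(tr)
#> Velocity track of synth (band B1)
#>   51 correlation intervals, 50 with propagation (98.0%)
#>   mean CV over defined intervals: 10.66 cm/s
#>   sectors:
#> south  east north  west
#>    26     8     8     8
recover_wave(tr, w)
#> $cv
#> [1] 10.07742
#> $sector
#> [1] "south"
```

The per-window estimates near the burst recover the programmed 10 cm/s
within lag quantization and the correct sector (30° lies in the south
sector); windows far from the burst see only noise and scatter across
sectors. The classification protocol on a synthetic 47 + 53 cohort whose
class effect mirrors the published direction (lower vertical percentage,
higher horizontal percentage and lower S2 sample entropy for the
preterm-like class):

```r
coh <- simulate_feature_cohort(seed = 7)
qda_cv(coh$x, coh$y, positive = "preterm", seed = 7)
#> <ehg_cvreport> QDA, 10-fold x 30 reps (SMOTE: whole; positive: preterm)
#>   features: P_V, P_H, SE_S2
#>   Se = 77.4%  Sp = 67.3%  CA = 72.4%  AUC = 77.7%
```

`run_pipeline(run_config(), "out/")` chains simulate → preprocess →
velocity → features → classify and writes hash-tagged CSV/JSON artifacts
plus a manifest; `inst/scripts/ehg-cli.R` wraps the same functions for shell
use.

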