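---
title: "Rule-based P wave detection in normal and pathological ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based P wave detection in normal and pathological ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(pwaved)
```

## The problem

The P wave marks atrial depolarization. It is the hardest ECG wave to detect
automatically: it is small (typically 0.1–0.25 mV against a 1–2 mV QRS), has
no distinctive spectral signature, and — crucially — in many arrhythmias it is
not where a naive detector looks for it. During atrial fibrillation (AFIB)
there is no P wave at all, only fibrillatory activity; before a premature
ventricular contraction (PVC) there is no conducted P; in second-degree
atrioventricular block (AVB II) a P wave appears *without* a following QRS,
stranded inside a long pause. Detectors that always search a fixed window
before each QRS therefore produce large numbers of false positives and false
negatives exactly in the recordings where P wave information matters most.

`pwaved` implements a detector that first establishes the rhythm context of
every beat and only then decides where — and whether — to search for a P wave.

## The pipeline

Eight stages run in order (`run_pipeline()`):

1. **QRS detection.** The cleaned signal is band-passed to 12–19 Hz, which
   enhances QRS complexes and suppresses P and T waves, and transformed by the
   *phasor transform* `PT(n) = atan(x(n) / Rv)` with `Rv = 0.001`. Candidate
   peaks are the largest local maxima in non-overlapping 300 ms windows; a
   candidate is accepted when its band-passed amplitude exceeds twice the
   local standard deviation in a centered 2 s moving window. Detections
   closer than 200 ms merge to the larger peak.
2. **Backward search.** When an RR interval exceeds 1.75 times its
   predecessor, the gap is re-scanned with a lowered threshold (30% of the
   last accepted QRS amplitude) to recover beats the adaptive threshold
   missed. The scan repeats until no interval fires, so it is idempotent.
3. **T wave.** Per beat, the T peak is the maximum of the phasor-transformed
   (`Rv = 0.1`) cleaned signal in `R(i) + 0.12·RR(i)` to
   `R(i) + 0.57·RR(i) + 60 ms`, with `RR(i)` the interval *following* the
   beat (the last beat reuses the preceding interval).
4. **PVC flagging.** The area under the QRS — the absolute integral of the
   baseline-free signal over `R(i) ± 150 ms` — is compared with 1.3 times the
   running median area of all previous non-ectopic beats. If more than 75% of
   all beats end up flagged, the morphology change evidently affects every
   beat and is reinterpreted as bundle branch block: all flags are cleared.
5. **AFIB flagging.** The heart-rate sequence `hr(i) = 60/RR(i)` is quantized
   into 15 bpm symbols; three consecutive symbols form a word; the Shannon
   entropy of the word distribution over a 59-beat window centered on the
   beat, normalized by `ln 59`, is thresholded at 0.737. When more than 30
   PVC-flagged beats fall inside the window, the entropy rise is attributed
   to the ectopy (PVCs are framed by short–long RR pairs) and the AFIB flag
   is withheld.
6. **Pathology gate.** AFIB first: an AFIB beat gets no P search at all.
   Otherwise a PVC beat skips the search before its QRS. Otherwise proceed.
7. **P search.** Conducted P: maximum of the phasor-transformed
   (`Rv = 0.05`) cleaned signal in `R(i−1) + 0.71·RR(i)` to
   `R(i) − 0.07·RR(i) − 60 ms` (first beat: the fixed window `R − 300 ms` to
   `R − 80 ms`). Dissociated P: when the gate opens — no dissociated P in the
   previous interval and `RR(i) > 1.6·RR(i−1)`, `RR(i) > 1.6 s`, beat not a
   PVC; or, immediately after one, simply `RR(i) > 0.8·RR(i−1)` — the pause
   `T(i−1) + 200 ms` to `P(i) − 400 ms` is searched the same way.
8. **Verification.** A candidate is accepted only if its absolute amplitude
   on the cleaned signal exceeds 5% of the QRS amplitude (otherwise the beat
   is likely of nodal or ventricular origin and has no P), and it lies after
   the previous T peak (otherwise it *is* the previous T). Rejected
   candidates are kept in the output with their rejection reason.

All window arithmetic converts seconds to samples through one shared
round-half-even helper, so window edges are identical across modules and
sampling rates.

## Worked example

```{r pipeline}
g <- generate_ecg(synth_ecg(fs = 360, duration = 60, hr_bpm = 60,
                            events = list(list(type = "pvc",
                                               beats = c(10L, 25L, 40L)))))
res <- run_pipeline(g$record)
res
evaluate_p(res$annotations, g$truth, tolerance = 0.100, fs = 360)[c("se", "pp")]
```

## Design choices in detail

**Where amplitudes are compared.** Peak *positions* are always taken on the
phasor signal; the arctangent is strictly increasing, so they coincide with
the positions on the underlying signal, and the transform's enhancement of
low-amplitude waves is what makes a single `argmax` per window a reliable
locator. Amplitude *ratios*, however — the 2·sd adaptive threshold and the
30% backward-search threshold — are compared in the band-passed domain. With
`Rv = 0.001` the arctangent saturates: on our fixtures the phase value at a
QRS is 1.566 while residual P-wave leakage already reaches 1.54, and twice
the local standard deviation of the phase signal exceeds π/2, so a literal
phase-domain threshold could never fire. The compression destroys exactly the
amplitude information a ratio test needs; before the arctangent, the same
ratios are well separated (QRS leakage ≈ 6× the P leakage in band).

**Band-pass order.** The 12–19 Hz FIR (Hamming window) uses order ≈ fs/2,
giving a ~6.6 Hz transition band. A longer filter suppresses out-of-band P/T
leakage further, but its longer ringing raises the very standard deviation
the adaptive threshold is built from: with order ≈ fs a beat at 0.4 relative
amplitude sits exactly at the threshold, while at fs/2 it clears it and P
leakage still stays below half the threshold. The filter's tap sum is removed
so the DC gain is exactly zero.

**Lynn high-pass.** Realized as the classic construction: two cascaded
moving averages (a triangular linear-phase low-pass) with the window length
`round(fs / 0.67)`, so the low-pass has its first spectral null at 0.67 Hz,
subtracted from the delay-compensated input. At 0.1 Hz the high-pass passes
only ~7% of a drift; at 10 Hz it is unity within 0.01%.

**PVC reference median.** The running median excludes beats already flagged
as PVC. A median over *all* previous beats is contaminated during sustained
bigeminy (half the beats are ectopic) and drifts upward until later PVCs fall
below 1.3× and are missed; excluding flagged beats keeps the reference tied
to the normal morphology. The first beat is never a PVC (no prior median).

**Entropy construction.** The symbolic-dynamics stage leaves the symbol bins
to the implementer, so they were calibrated once against the fixed 0.737
threshold on synthetic rhythms: with 15 bpm bins, sinus rhythm with up to
~5% RR jitter stays below the threshold for rates up to ~120 bpm (median
normalized entropy ≤ 0.52), while RR jitter of 25% or more — the
fibrillation surrogate — exceeds it decisively (median ≥ 0.85). Narrower
bins (5 bpm) misclassify ordinary sinus variability above ~90 bpm as AFIB;
wider bins (20 bpm) leave almost no margin at the threshold for slow AFIB.
Sinus tachycardia at 180 bpm with a full 5% jitter would still cross the
threshold — in practice sinus variability shrinks as rate rises, and the
limitation is noted here rather than patched with a rate-dependent bin.
Entropy is normalized by `ln 59` so it lies in [0, 1]; beats whose 59-word
window would leave the record have no entropy and are never flagged, which
trades a known edge effect (the first and last ~30 beats cannot be called
AFIB) for zero spurious calls on short records.

**Dissociated-P window right edge.** The printed window ends at
`P(i) − 400 ms`, with `P(i)` the conducted P of the closing beat. When that
beat has no accepted P, the left edge of its normal search window stands in,
keeping the dissociated search strictly left of any plausible conducted-P
territory.

**Ties and degeneracy.** Every argmax breaks ties toward the earliest
sample. Windows that are empty after clipping mean "wave undefined for this
beat", never an error. Records shorter than 2 s are refused by the
detectors.

**Evaluation matching.** Detected peaks are matched to reference peaks
one-to-one within ±100 ms by a two-pointer scheme (each detection takes the
earliest unmatched reference within tolerance), which attains the maximum
possible number of matches on sorted series. The tolerance is an explicit
argument everywhere because published beat-level figures rarely state
theirs, and it is the main comparability caveat when numbers are placed side
by side. Multi-record summaries report the unweighted per-record mean (the
convention in the delineation literature) alongside the pooled
micro-average; a record with no reference P and no detections has undefined
sensitivity and is excluded from the mean rather than counted as 0 or 100.

## The synthetic generator, and what passing it does (not) show

`synth_ecg()`/`generate_ecg()` build ECG as parametric waves on a zero
baseline: a Gaussian P (default 0.15 mV, σ 20 ms), a Ricker (Mexican-hat)
QRS (1.0 mV, σ 12 ms) whose negative side lobes play the role of the Q and S
deflections and keep the net QRS area near zero — as in real ECG, where
baseline removal must not shift the neighbourhood of a beat — and a Gaussian
T (0.30 mV, σ 40 ms). Wave timings scale with the local RR interval (P at
`R − (0.18·RR + 30 ms)`, T at `R + (0.345·RR + 30 ms)`), mimicking the
physiological shortening of the PR and QT intervals at fast rates and
keeping every wave inside its search window for 40–180 bpm. Bump centers are
snapped to the sample grid, so truth indices are exact and localization can
be asserted to ±1 sample.

Pathology surrogates follow the same logic: a PVC keeps a sharp narrow
component (so it remains visible to the band-pass detector, as real PVCs
are) plus a broad biphasic hump that multiplies its absolute area without
adding net area, and has no P; an AFIB segment redraws RR i.i.d. with ≥25%
jitter and removes P waves; an AVB II event deletes QRS and T but retains
the P; a bundle-branch-block surrogate widens every QRS.

Problem sizes used by the test-suite and the acceptance script — 30–240 s
records at 128–360 Hz, cohorts of a handful of records — were chosen as the
smallest sizes at which every rule (including the 59-beat entropy window)
is exercised with full interior windows.

What these fixtures do **not** emulate: noise and artefact (the detector is
explicitly not designed for noisy ECG), f-waves during AFIB (absent P is
emulated by absence, not by fibrillatory activity), biphasic or inverted P
and T waves, and real QRS morphology variety. Passing the suite therefore
demonstrates that the decision logic and window arithmetic are implemented
exactly, and that each rule fires on the rhythm pattern it targets — it does
not certify clinical performance. Performance on real recordings should be
measured with the evaluator on PhysioNet databases with P annotations
(MITDB with its P-wave annotation set, QTDB, BUT PDB), which requires
downloading those databases.

## Known limitations

* T detection takes the literal phase maximum, so deeply inverted T waves
  are mislocated (and an inverted-T beat can then corrupt the position
  criterion of its successor's P).
* Third-degree AV block — P and QRS fully independent — is out of scope: the
  dissociation gate models dropped beats, not an independent atrial clock.
* The AFIB stage needs 59 beats of context; the first and last ~30 beats of
  a record (or of a rhythm change) carry no entropy and cannot be flagged.
* The `clean_ecg()` stage (Lynn high-pass + 50/60 Hz notches) is a minimal
  pre-cleaning front end, switchable off via `clean_enabled`; it is not a
  full denoising chain.
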