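---
title: "Automated vigilance-state scoring of rodent single-channel EEG: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated vigilance-state scoring of rodent single-channel EEG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(somnoscore)
```

## The problem

Rodent sleep studies score each 10-s epoch of a polysomnographic recording
as wake (W), NREM sleep (NR) or REM sleep (R). Manual scoring of 24-h
recordings is slow and subjective, and most automatic methods either need an
EMG channel or training data. `somnoscore` scores the three states from a
*single* EEG channel with no training, using only unsupervised 2-component
Gaussian mixture models (GMMs) over spectral-band features, plus a handful
of physiologically motivated post-processing rules.

The central difficulty is that wake and REM sleep look alike in a single
EEG channel: both are low-amplitude with prominent theta (5–10 Hz)
oscillations. NREM sleep, in contrast, is easy — high-amplitude delta
(1–4 Hz) waves and sigma-band (11–16 Hz) sleep spindles. The pipeline
therefore splits the 3-class problem into two binary ones: NREM vs. the
wake/REM mixture (easy, solved first), then REM vs. the wake/NREM mixture
(hard, solved by a dedicated multi-step procedure).

## Pipeline overview

1. **Preprocessing** — round a non-integer sampling rate to the nearest
   integer (polyphase resampling), optionally high-pass filter (2 Hz
   cutoff, 0.6 Hz transition, zero-phase FIR), and cut the signal into
   10-s epochs.
2. **Artifact rejection** — two channels:
   *Amplitude*: the per-epoch RMS is smoothed over a ±1-epoch window by
   the root-mean-of-squares operator
   \[ X'_n = \sqrt{\tfrac{1}{|W_n|}\textstyle\sum_{j \in W_n} X_j^2}, \]
   a 2-component GMM is fitted, and epochs outside
   \(T_\mathrm{high} = M_\mathrm{high} + 4\sigma_\mathrm{high}\),
   \(T_\mathrm{low} = M_\mathrm{low} - 4\sigma_\mathrm{low}\) are flagged.
   *Density*: in the z-scored plane of (raw RMS, summed 2–10 Hz spectral
   amplitude), epochs whose Epanechnikov-kernel density estimate has
   natural-log density below −5 are flagged. Flagged epochs are excluded
   from all further analysis and restored at the very end with the label
   of the closest preceding scored epoch.
3. **NREM detection** — for each band in a species preset (default:
   2–3, 3–4 and the five 1-Hz sigma bands 11–16 Hz), the raw multi-bin
   spectral chunk (epochs × bins, amplitudes not summed) is clustered by a
   full-covariance 2-component GMM; the higher-amplitude component is
   NREM. A majority vote across bands (ties to the mixture class) gives
   the NREM mask.
4. **Wake reduction** — the smoothed RMS is smoothed again with a wide
   window (150-s half-width). Because REM always follows NREM, the wide
   window "drags" the high NREM amplitude across the NREM→REM transition,
   so REM epochs stay in the high regime while consolidated wake stays
   low. A 2-component GMM splits the series; the equal-posterior boundary,
   lowered by 10% of the inter-mean gap, is the retention threshold, and
   45 retained epochs after each upward crossing (the ascending slope) are
   also dropped.
5. **REM identification** — for each *band combination* (BC: a theta band
   5–10 Hz paired with a delta/sigma band), two 1-D GMM steps on the
   retained epochs: first remove the higher-delta component (the NREM
   bulk), then label the higher-theta component of the remainder as REM.
   An epoch is REM when more than a stringency fraction of the BCs agree.
6. **Ellipse correction** — a single Gaussian is fitted to the averaged
   z-scored (theta, delta/sigma) features of the high-stringency REM
   epochs (vote count ≥ 80% of the maximum); every epoch within 1.5
   Mahalanobis-SD of its center becomes REM. A manual polygon contour is
   available when the automatic ellipse is inadequate.
7. **Contextual rules** — (i) a REM run with ≥10 wake epochs among the 20
   preceding an epoch is relabeled to the preceding state (REM does not
   arise from a wake-rich context); (ii) optionally, singleton REM epochs
   take the preceding label.
8. **Second iteration** — within each above-threshold segment, epochs
   between the threshold crossings and the outermost first-iteration REM
   epochs are dropped (ascending and descending slopes), and steps 5–7 are
   repeated on the cleaner retained set.

## Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| epoch length | 10 | s | field standard for rodents |
| RMS smoothing half-width | 1 | epochs | 20-s reach; variance reduction without merging states |
| amplitude threshold width | 4 | component SD | tail bound; boundary mass negligible |
| KDE log-density threshold | −5 | log density | on z-scored features this is data-independent |
| wide smoothing half-width | 150 | s | 150–300 s retains ≥95% of REM with the automatic threshold |
| threshold drop | 0.10 | fraction of mean gap | pushes the boundary below the REM margin |
| post-crossing removal | 45 | epochs | ascending slope is wake/early NREM; REM never occurs there |
| rat BCs | 4 | — | theta 6–8/6–9/5–8/5–9 vs delta 3–5/3–6/3–5/4–6 Hz |
| rat stringency | 0.75 | fraction | unanimity over 4 BCs; see below |
| ellipse magnification | 1.5 | SD | reclaims false-negative REM deep in the cluster |
| iterations | 2 | — | second pass suppresses false-positive REM |

Thresholds are strict inequalities throughout; values exactly at a
threshold are kept.

### Design choices in detail

**Smoothing normalizer.** The root-mean-of-squares smoother normalizes by
the true (edge-truncated) window size `2w+1`, so a constant series is a
fixed point and `w = 0` is the identity; at the series edges the window
shrinks rather than padding.

**Robust artifact mixture.** The amplitude GMM is fitted on the central
96% of the smoothed RMS (2% trimmed per tail) and the fitted components
are then applied to all epochs. Without trimming, EM can place a component
directly on a cluster of extreme artifacts — exactly the regime where the
4-SD rule must not be anchored to the artifacts themselves. Both
thresholds can also be set manually.

**Band membership and spectra.** Per-epoch spectra are Welch-style means
of |DFT| amplitudes (not power) over 256-sample Hanning windows with 50%
overlap; a band is the half-open interval `[lo, hi)` over bin centers, so
adjacent bands partition the axis and band features are additive.

**No-NREM guard.** A 2-component GMM always partitions its input, even
when no NREM sleep exists. `nrem_detect()` therefore checks the ratio of
the two components' mean total amplitudes in every band: genuine NREM
gives ratios of 2–5 in at least one delta band, whereas splitting a
homogeneous state yields components differing only by slow amplitude
drift (≲1.3). If no band reaches 1.5, the record is scored NREM-free.

**GMM boundary in wake reduction.** "The boundary between the components"
is implemented as the equal-posterior decision boundary of the 1-D
mixture, searched between the component means, with a variance-weighted
midpoint as fallback.

**Stringency.** For rats the default is unanimity over the 4 default BCs
(`stringency_fraction = 0.75`, i.e. vote count must exceed 3 of 4). The
alternatives were calibrated with the packaged sensitivity screen on
synthetic reference recordings: epochs at NREM/REM boundaries carry
genuinely mixed spectral content and pass 3-of-4 voting, costing ~10
points of REM precision, while unanimity balances REM precision and
recall at ~0.93 before the contextual rules. Mice default to strict
majority over 15 BCs. Any fraction in (0, 1] may be set; raising it never
adds REM epochs.

**Default band combinations.** The packaged per-species BC defaults were
selected by running the screen over the theta × delta/sigma grid on
synthetic reference data, constrained to the effective ranges (7 Hz
centrally positioned in the theta band; narrow low-delta bands that do
not overlap the theta range, so the step-1 delta split cannot absorb REM
epochs after the second-iteration trim). When the user has an expert
hypnogram, `band_sensitivity_screen()` re-ranks candidates for their own
data — that, not the shipped default, is the recommended path for a new
preparation.

**Rule order and artifact restoration.** The wake-history rule runs
before the singleton rule; both run on the artifact-free label sequence,
and artifact epochs are restored afterwards from the closest preceding
scored epoch (leading artifacts take the following label). Both rules are
idempotent; the wake-history rule judges each run against the
progressively updated labels, which makes a single pass a fixed point.

## The synthetic polysomnography generator

`simulate_psg()` provides seeded ground-truth data with the statistical
structure the pipeline exploits:

* **Hypnogram** — a semi-Markov bout model with a 12:12 light/dark cycle
  (wake fraction 0.25 in the light, 0.65 in the dark phase; overall
  fractions 0.45/0.45/0.10 for W/NR/R). Consolidated wake episodes
  alternate with sleep phases containing a geometric number of
  NREM(–REM) cycles separated by brief arousals. REM entry probability is
  derived from the configured fractions and bout means; an NREM bout that
  transitions into REM lasts at least 12 epochs (REM latency), and every
  REM bout directly follows NREM. Bout lengths are geometric (capped at
  3× their mean), and the mean of the next consolidated wake bout and
  sleep phase absorb part of the realized-vs-target drift so that
  recordings of ≥12 h land within ±5 percentage points of the configured
  fractions. The default wake bout scale equals the NREM scale because
  the cycle structure forces equal wake and NREM bout *counts*, so the
  stage-fraction ratio is the bout-mean ratio.
* **EEG** — per stage, narrowband oscillators (delta 2.5 Hz, theta 7 Hz,
  burst-modulated sigma 13 Hz spindles) with drifting frequency and
  amplitude plus 1/f broadband noise; default stage RMS ≈ 22 (wake),
  47 (NREM), 33 (REM) units. A shared lognormal amplitude drift (13%,
  ~200-s correlation) reproduces the within-state RMS variability of real
  recordings. Stage transitions complete within ~2 s; NREM onsets (and
  offsets into wake) additionally ramp over 2 epochs, exercising the
  wide-window smoothing behavior.
* **Artifacts** — high-amplitude movement-like transients, mid-epoch
  flatline dropouts of 6–12 epochs, and normal-amplitude events (added
  high-frequency muscle-like power, or 2–10 Hz broadband grooming-like
  bursts) at ~2% of epochs overall, mostly during wake.

What the generator does **not** emulate: real neural dynamics (no neural
mass model), EMG, inter-animal spectral variability, electrode drift
across days, and — importantly — artifacts that are spectrally
indistinguishable from physiology in the (RMS, 2–10 Hz) feature plane.
Passing tests on synthetic data therefore demonstrate the pipeline's
mechanics and internal consistency, not its accuracy on any particular
laboratory's recordings; the packaged screen plus an expert hypnogram
remain the calibration path for real data.

## Problem sizes and numerical choices

The packaged tests and the acceptance script run on 24-h recordings at
104 Hz (8640 epochs), the recording scale the method targets; wake
reduction is checked over five seeds and the full pipeline over three.
All GMMs are `mclust` fits with deterministic model-based hierarchical
initialization (on a fixed-seed subset of ≤1500 points for large inputs),
so a configuration fully determines the output. Degenerate inputs
(all-equal series, bands without bins, self-intersecting polygons, fewer
than 10 high-stringency epochs for the ellipse) raise errors that name
the remedy; a BC whose GMM degenerates abstains from the REM vote rather
than failing the run.

## Known limitations

* Epochs at NREM/REM transitions carry mixed spectral content and remain
  the main error source, as they are for human scorers.
* The wake-reduction premise requires consolidated wake; recordings that
  are pathologically fragmented (or contain no NREM at all) fall back to
  conservative behavior (threshold warnings, the no-NREM guard) but are
  outside the method's design envelope.
* Heavy artifact contamination (≫4% of epochs) degrades both artifact
  channels; the amplitude GMM and the ellipse correction are the first
  casualties. Manual thresholds and the polygon contour are provided for
  exactly these cases.
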