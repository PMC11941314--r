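---
title: "Repetition-range probability profiling of Holter dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repetition-range probability profiling of Holter dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiorep)
```

## The model

A 21-hour Holter recording yields on the order of 10^5 beats.  The method
implemented here discards temporal order entirely and works with the
*repetition profile*: for each distinct heart-rate value, the number of beats
carrying that value over the whole recording.  The modelling claim is that
different cardiac dynamics load this profile differently — not in *which*
heart rates occur (all dynamics live between roughly 55 and 105 bpm) but in
*how many* values recur at characteristic rates and where they sit on the
heart-rate axis.

The analysis restricts the profile to repetition ranges.  With the default
configuration there are two, chosen to partition the 1000–3000 band with no
gap or overlap:

* **P1**: repetition counts in [1000, 2000] (inclusive on both ends),
* **P2**: counts in [2001, 3000].

Entries surviving the filter are the range's *qualifying pairs*.  Within a
range, qualifying pairs are treated as equally probable elementary events, so
a 5-bpm heart-rate group ℓ (every value is labelled by its nearest multiple
of 5) has probability

$$ P(\ell) = \frac{\#\{\text{qualifying pairs labelled } \ell\}}{n}, $$

with $n$ the number of qualifying pairs.  Each range is condensed to the
**summed top probabilities** $S$: the sum of the two largest values of
$P(\cdot)$.  A concentrated ("loaded") profile pushes $S$ toward 1; a profile
spread evenly over many groups pushes it down.  Degenerate cases are defined
explicitly: $S$ is the single probability (hence 1) when exactly one pair
qualifies, and 0 when none does; the feature record flags the single-pair
case so the classifier can distinguish a structurally trivial 1 from a
genuinely loaded one.

## Classification bands

Each dynamics class is a conjunction of inclusive interval predicates on the
per-range features, evaluated by `classify()` with the reference values in
`default_bands()`:

| feature | normal | chronic | acute | pacemaker |
|---|---|---|---|---|
| P1 qualifying pairs | 11–14 | 21–31 | 9–11 | 4–5 |
| P2 qualifying pairs | 0–3 | 10–14 | 3–6 | 2 |
| P1 summed top prob. | 0.35–0.46 | 0.35–0.48 | 0.5–0.6 | 0.5–0.6 |
| P2 summed top prob. | 0–1 | 0.54–0.7 | 0.46–0.75 | 1 |
| qualifying labels (bpm) | 55–95 | 65–105 | 75–100 | 60–75 |

A supplementary rule uses the largest *single* label probability: normal
dynamics peak below 0.3 in every range, the other classes at or above 0.3 in
some range.  Two design points deserve comment:

* **Single-pair ranges are exempt from the peak rule.**  The normal
  reference profile has exactly one qualifying P2 pair, whose probability is
  necessarily 1; applying the "< 0.3" rule there would reject the reference
  case of its own class.  The rule therefore only examines ranges holding at
  least two qualifying pairs.
* **"At or above" rather than strictly above 0.3.**  The chronic reference
  profile's own maxima are 6/23 ≈ 0.26 (P1) and exactly 3/10 = 0.3 (P2).  A
  strict > 0.3 reading would misclassify the chronic reference itself, so the
  loaded-class rule is implemented as ≥ 0.3 in at least one eligible range.

The combination rule is deliberately conservative: *all predicates of exactly
one class must pass*.  The bands overlap in places (normal and chronic share
most of the P1 summed-probability interval; P2 separates them), and when zero
or several classes pass the call is `unclassified`, never a forced guess.
Every predicate's verdict is returned in the audit trail.  Bands are
externalized to JSON (`read_bands()` / `write_bands()`) so they can be
recalibrated on other cohorts; whether the reference bands generalize beyond
the cohort they were derived from is an empirical question this package does
not answer.

## Numerical conventions

* Probabilities are ratios of small integers and are carried at full
  precision; `sum(label_probs)` is 1 to ≤ 1e-12 and tested as such.
* Published summary tables print probabilities at 2–3 decimals and —
  verifiably, in every reproducible cell — sum the *displayed* two-decimal
  values: the acute P1 statistic appears as 0.27 + 0.27 = 0.54 where full
  precision gives 6/11 ≈ 0.5455.  `top_sum(dist)` is full-precision and
  drives classification (0.5455 lies inside the acute 0.5–0.6 band either
  way); `top_sum(dist, digits = 2)` reproduces the published arithmetic and
  is what the acceptance report emits, since it is the scale those tables
  print.
* Interval membership uses a 1e-9 tolerance at the closed endpoints so that
  rationals reassembled from floating point (0.3 + 0.3 against a 0.6 bound)
  compare sanely.
* Ties in the "two largest probabilities" need no tie-break: only the two
  largest *values* of the descending sort are summed, whichever labels carry
  them.  `peak_labels` reports all argmax labels.
* Beat-level heart rate from RR intervals is defined as
  `round_half_up(60000 / RR_ms)` in integer bpm — the display resolution used
  throughout the field.  Profile machinery, however, accepts sub-integer
  heart-rate values, for the reason below.

## Half-bpm resolution in the synthetic generator

A 5-bpm group contains only five integers (e.g. 88–92 for label 90), yet the
chronic reference profile holds **six** distinct repetition counts in its
90-bpm group.  Whole-recording, per-distinct-integer counting therefore
cannot realize that profile.  The generator instead assigns distinct values
at half-bpm steps around the group center — offsets 0, ±0.5, ±1, ±1.5, ±2,
all exactly representable doubles, never crossing a label boundary — which
accommodates up to nine counts per group.  This is a representational choice
only: repetition counting distinguishes stored values, and text round trips
(`%.10g` formatting) preserve halves exactly.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` states a target profile: (heart rate, count) pairs inside
the analysis ranges, plus background pairs whose counts fall outside them
(below 1000 or above 3000).  `generate_recording()` emits exactly `count`
beats per value, shuffles them with a seeded RNG, and accumulates timestamps
at RR = 60000/hr ms per beat, the first beat at *t* = 0 (so 100 beats at
60 bpm span 99 elapsed seconds — duration is last-minus-first timestamp).
The defaults are the stated world of the reference cohort: the four
`prototype_spec()` classes reproduce the published (label, count) multisets
exactly, and the background — three bulk values with counts above 3000
(for the pacemaker, a dominant paced rate) sized to bring the recording to
≈ 21 h, plus two sub-1000 stragglers (counts 420 and 730) — is plausible
filler chosen once, because real recordings' out-of-range mass is entirely
unreported.

Per-count jitter is validated against the range boundaries: a spec is
rejected whenever any count could cross into or out of its repetition range
(the acute reference holds a count of 2999, capping safe jitter at 1).
Within that guarantee, jitter provably cannot change any per-range feature —
pair counts and label probabilities depend only on range membership — which
is why a jittered cohort still classifies perfectly.

Deliberately **not** modelled: RR-interval autocorrelation, HRV spectra,
circadian trends, ectopy, artifact.  The analysis is order-invariant by
construction, so temporal realism would not change any computed feature.  A
green end-to-end test therefore establishes that the pipeline computes the
intended statistics and that the bands separate the reference profiles — it
does *not* establish clinical performance on real recordings, where profile
shapes between the reference prototypes, measurement artifact, and
out-of-band dynamics occur.  The blind-study surrogate (sensitivity =
specificity = κ = 1 on a zero-jitter synthetic cohort) mirrors the reported
headline result only in the sense that recordings realized *from* the
reference profiles are recovered perfectly.

## Evaluation conventions

All three statistics are one-vs-rest per class: sensitivity TP/(TP+FN),
specificity TN/(TN+FP), and Cohen's κ = (p_o − p_e)/(1 − p_e) on the
dichotomized 2×2 table.  Undefined ratios (zero denominators) are reported
as absent (`NA`), never as 0; when p_e = 1, κ is 1 under perfect agreement
and absent otherwise.  How indeterminate calls were scored in the original
blind study is not stated anywhere; here `unclassified` predictions count as
negative for every class — a convention that can only penalize the
classifier.  A pooled multi-class κ is reported for convenience but is not
part of the acceptance surface.

## Known limitations

* The reference bands encode a 76-recording cohort summarized in print; they
  are configuration, not truth.  Values outside 55–105 bpm or profiles whose
  features straddle band boundaries return `unclassified`.
* Whether the original repetition counts were computed over the whole 21 h
  or per sub-period is not documented; this package adopts the
  whole-recording reading (the only one consistent with several distinct
  counts per 5-bpm group) and does not implement hourly counting.
* One published tally ("Total 14" under the acute P2 column) is inconsistent
  with its own four listed rows and with the per-label probabilities printed
  alongside (0.25/0.5/0.25); the row listing governs here, and the
  discrepancy is recorded rather than repaired.
* Beat CSVs are the only raw-input format; vendor Holter formats, EDF/WFDB,
  and QRS detection are out of scope.

```{r example}
features <- extract_features(profile_from_table(prototype_table("acute"), "acute"))
features
classify(features)$predicted
```
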