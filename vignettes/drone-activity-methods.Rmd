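---
title: "Methods: reconstructing drone hive-entrance activity from dual-sensor RFID logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing drone hive-entrance activity from dual-sensor RFID logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droneactivity)
```

## The measurement model

A tagged drone crossing the hive entrance is read by two patch antennas,
labelled A (hive side) and B (outside). The reader does not observe
direction; direction is *reconstructed* from the order of reads. The
crossing grammar is:

* departure: the tag crosses A, then B, then is read at B again —
  the triple (A, B, B);
* arrival: the mirror triple (B, A, A);
* the event time is the timestamp of the **middle** read of its triple.

A complete round trip therefore reads as the five-read series
A, B, B, A, A: the drone's return to the outer sensor both closes the
departure and opens the arrival, so **matched triples may share their
boundary read**. This one modelling decision fixes the matcher semantics:

* matching is a greedy left-to-right scan per tag;
* on a non-match the scan advances one read (the skipped read is tallied
  as unmatched, never silently dropped);
* after a match the scan continues *at* the triple's third read, so that
  read may begin the next triple.

Under these semantics the per-event triple streams the simulator emits
(A,B,B then B,A,A — six reads per round trip) and the shared-boundary
five-read series both parse into exactly one departure plus one arrival
with correct middle timestamps. The test suite checks the scan against an
independently implemented oracle (recursive leftmost regex matching on the
remaining suffix) on every sensor sequence of length ≤ 8 — 510 sequences —
and on random longer noise.

Two reconstruction imperfections are first-class outputs rather than silent
repairs. Consecutive same-kind events (a missed complement read) are kept
and counted (`n_inconsistent_transitions`), and the spans they bound are
marked `broken` and excluded from duration statistics. An optional
*lenient* mode emits an unmatched (A, B) pair that immediately precedes a
matched arrival as an inferred departure; under the shared-boundary
semantics this situation is in practice already subsumed by the strict scan
(the pair plus the arrival's first read form a matchable triple), so the
mode exists for contract completeness and is tested to add nothing on
simulated noise. Debouncing (collapsing same-sensor repeats closer than
`debounce_s`) defaults to **off**, because the grammar's double-B/double-A
signature is itself a same-sensor repeat; any nonzero value must stay below
the intra-triple read gap (~1–2 s).

## Spans, censoring, and behavior categories

Time outside the hive is the span from a departure to the next arrival;
time inside is the span from an arrival to the renewed departure. A leading
arrival opens a left-censored outside span, a trailing departure a
right-censored one (the drone never returned), and same-kind event pairs
bound `broken` spans. Only uncensored spans carry durations.

Categories are a pure function of location, duration and censoring, with
lower-exclusive/upper-inclusive edges: outside spans are `exit_entry`
(≤ 3 min), `short_mission` (3–10 min, orientation flights), `scouting`
(10 min–10 h, DCA search), or `extended_absence` (> 10 h); inside spans are
`brief_inside` (≤ 30 min) or `resting` (> 30 min); a right-censored outside
span is a `departed_drone`. Conventions worth making explicit:

* **noon cutoff** — "morning" is clock time in [00:00, 12:00); 12:00:00
  itself is afternoon.
* **days away** — `floor(d / 24 h) + 1`, so a 24–48 h absence is "2 days".
  The field usage distinguishes "outside for 24 h" from "two to three
  days"; the exact convention is not standardised, so it is kept as a
  documented, configurable choice.
* **sub-second spans** — durations below 1 s are physically implausible
  double-counts and are classed `unresolved`; a span of exactly 1 s is a
  valid `exit_entry`.
* **long rests** — inside spans beyond the 10 h table bound stay `resting`
  with a `long_stay` flag (stays of up to four days are observed), rather
  than acquiring a category of their own.
* **flights** — a "flight" is a *completed* departure→arrival pair.
  Final censored departures are reported separately
  (`n_censored_departures`), which keeps per-drone flight means well
  defined. Mean flights per drone can be read per whole study or per
  active day; the two definitions differ and both are computable from the
  daily series, so neither is hard-coded.

## The simulator: a stated world

`simulate_traffic()` is an agent-based generator whose defaults *are* the
monitored season: 200 tagged drones, 45 days (15 Oct–28 Nov), 8% of tags
never read, 10% read exactly once, flight durations drawn from the four
classes with weights 7.3 / 76.22 / 12.4 / 4.0 percent (renormalised — the
printed shares sum to 99.92%), 21.5% of the cohort morning-active, 16%
active in both periods, a 15:00 modal departure, and four weather-shutdown
dates (two hot, two rainy) with no departures at all.

Design choices, made once:

* **Period profiles.** Morning/afternoon activity is a per-drone trait.
  Since only flying drones (a fraction `1 − p_never − p_single` of the
  cohort) can realise it, the per-flyer morning probability is
  `morning_active_fraction / (1 − p_never − p_single)` so the *cohort*
  fraction has the configured expectation. Each morning-active drone's
  first flight is forced into a morning clock-time component, and
  both-period drones also get one forced afternoon flight, so a drone's
  trait is always realised in its record (a drone flagged "both" must have
  ≥ 2 flights, which the generator guarantees).
* **Departure clock times** come from a four-component truncated-normal
  mixture: dawn ~03:00, early morning ~06:30, mid morning ~11:00
  (truncated strictly below noon), afternoon ~`afternoon_peak_hour`
  (default 15:00, the observed peak; the component weights default to
  0.04/0.07/0.09/0.80). Morning-only drones draw from the first three,
  afternoon-only drones from the last.
* **Flight counts** are Poisson per day with a gamma-heterogeneous
  per-drone rate (shape 1), producing the observed "few drones with many
  flights, many drones with few". Scheduling conflicts (a drone cannot
  depart while still outside) thin the realised totals ~15–20% below the
  nominal `mean_total_flights`; the realised mean is reported by the
  pipeline, not assumed.
* **Drifting** (1–3 day absences) is modelled as a tail of the over-60-min
  class (`p_drift` is the probability that an over-60-min flight extends
  to 1–3 days) rather than as an override of any flight's class — this
  keeps `behavior_mix` the true class distribution, so parameter-recovery
  tests measure the pipeline, not a biased generator. Permanent
  departures (`p_permanent_departure`, per scouting-or-longer flight)
  terminate the drone's record with an unpaired departure.
* **Inside gaps** between flights are implied by the daily scheduling
  rather than drawn from their own distribution: the departure-time
  mixture and an inter-flight gap distribution cannot both be imposed, and
  the field reports departure times, not gap distributions. Multi-day
  inside stays are injected separately (`p_long_rest`, 1–4 days).
* **The read channel.** Every true crossing emits its grammar triple with
  1–2 s intra-triple gaps at whole-second resolution; each read is
  retained with probability `p_read` (default 1 — the deployed reader's
  within-range reliability was not quantified, and read loss is exercised
  explicitly in tests); spurious reads are same-tag same-sensor duplicates
  at ±1 s, `p_spurious` per real read. Flights departing near the window
  end may return after it; the truth log keeps those arrivals so that
  per-tag events always strictly alternate and a final unpaired departure
  occurs *iff* the drone permanently departed.
* **Weather.** One row per day; shutdown dates get ≥ 38 °C (first half)
  or ≥ 14 mm rain (second half), normal days stay in the 16–36 °C /
  0–12 mm spring range. The generator does not encode any *positive*
  temperature–activity link on normal days, so weather correlations on
  simulated data reflect only the shutdown mechanism.

A single RNG stream from `seed` governs every draw; runs are
bit-reproducible, and the whole pipeline (`run_pipeline()`) writes
byte-identical artifacts for a fixed seed.

What a green test does — and does not — establish. The simulator emulates
the behavioural *structure* of entrance traffic: detection-failure and
loss rates, the duration mix, period profiles, circadian placement,
drifting, shutdown days. It does not model antenna physics, tag-collision
bursts, queen/worker traffic, reader downtime, or any drone-age structure.
Recovery tests therefore establish that the pipeline inverts the stated
read channel correctly, not that the channel is a complete model of any
particular deployment.

## Numerical and statistical choices

* Timestamps are local civil time held as POSIXct in the "UTC" zone
  (never offset), serialised as ISO 8601 without zone designator, at 1 s
  resolution — clock arithmetic (the noon cutoff, hour bins) is exact and
  DST-free.
* Mann–Whitney U is reported as min(U₁, U₂); the p-value is exact by full
  enumeration for n₁, n₂ ≤ 8 without ties, otherwise a tie-corrected
  normal approximation with continuity correction. Two-sided throughout.
* The flight-count chi-square defaults to three ranges (1–9, 10–29, 30+)
  against uniform expectation, df = 2; the bin edges are configurable
  because the original ranges are not printed.
* Pearson correlations use the two-sided t test; a constant series makes
  r undefined and is reported as NA with an explanatory tag, never as 0.
* Degenerate inputs fail loudly: unsorted reads, unknown sensor labels,
  out-of-order events, zero cohorts, overlapping group windows and
  non-positive expected counts are hard errors; malformed log lines are
  rejected *and counted*.

## Known limitations

* The A/B hive-side assignment is a labelling convention; the grammar is
  taken as given and nothing downstream depends on which antenna is
  physically inboard.
* Multi-day flights are attributed to their departure date in the daily
  series, so an arrival-heavy shutdown day can legitimately show zero
  flights while recording arrivals.
* Classification is duration-based only; it cannot distinguish drifting
  to another colony from a long DCA stay, nor mating success from loss —
  exactly the ambiguity the category names preserve.
* The statistics module reproduces the *procedures* (U, chi-square
  structure with df = 2, weather correlations), not any particular
  published values, which would require the original raw logs.
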