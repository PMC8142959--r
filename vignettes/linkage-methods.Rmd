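---
title: "Deterministic ambulance-to-ED linkage: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic ambulance-to-ED linkage: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edlink)
```

## The linkage problem

UK ambulance services and hospital trusts are separate organisations, and
the NHS number is rarely captured in prehospital records, so ambulance and
emergency department (ED) data cannot be joined on a patient identifier.
What both systems do hold are two *event* identifiers generated
automatically at the emergency call:

* the **CAD number** — the Computer Aided Dispatch incident number, a 1–4
  digit integer that resets at midnight and is unique within the service
  per day;
* the **call sign** — the crew's vehicle-shift identifier, a short
  letters-then-digits token under which several patients may arrive at one
  ED during a shift.

Because both are machine-generated on the ambulance side, their error rate
is low enough for *deterministic* (pass/fail, exact-agreement) matching,
which is otherwise a rare situation in record linkage. The catch is the ED
side: identifier recording there is manual and inconsistent across trusts —
separate fields at some, one unformatted free-text box at others, CAD only
at others still — and a substantial fraction of rows carry no identifier at
all.

`edlink` implements the complete pipeline: a ground-truthed synthetic data
generator, a transfer-format validator, the identifier cleaning rules, the
two-pathway deterministic linkage, and evaluation including the
precision/recall and false-non-link figures that a de-identified real study
cannot compute (re-identification being barred, a real study cannot inspect
its non-matches).

## The matching model

An ED row is linkable only if it carries at least one parsed identifier.
With two identifiers available, agreement on any *one* suffices to declare
a link, with a fixed precedence:

1. **CAD + date.** Look up (CAD, ED arrival date) in the ambulance data;
   if absent, look up (CAD, arrival date − 1), flagged
   `consecutive_date_used`, for care that crossed midnight. No times are
   compared: CAD plus date is unique on the ambulance side by construction.
   Records violating that uniqueness (data errors) are quarantined from CAD
   matching rather than guessed.
2. **Call sign + date + arrival time.** Candidates share the call sign on
   the arrival date (or the previous date); among candidates at the row's
   own site, the one whose ambulance-recorded ED arrival is nearest the
   ED-recorded arrival is accepted if within the tolerance window. Time
   only ever corroborates — it is never a standalone key — and an exact tie
   between two candidates is ambiguous and yields no match rather than a
   guess.

The CAD pathway runs first; the call-sign pathway is consulted only when
CAD yields nothing. Every row yields exactly one result: `cad_date`,
`callsign_datetime`, `unmatched`, or `no_identifier`.

### Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `time_tolerance_minutes` | 120 | Hospital hand-over delays make the gap between ambulance-recorded and ED-recorded arrival hard to bound; no authoritative window exists, so it is a surfaced, logged parameter. Call-sign match counts are provably monotone in it (tested). |
| `allow_consecutive_dates` | `TRUE` | Only arrival date − 1 is tried: the CAD is generated at the call, which always precedes ED arrival, so the ED date can never be *earlier* than the incident date. |
| `require_site_agreement_callsign` | `TRUE` | A call-sign shift conveys to one ED in this model, and cross-site call-sign collisions are plausible; requiring site agreement removes them. |
| `cmp_site_cad` | `"flag"` | Paramedics occasionally record the wrong destination, so a CAD+date match at a different site is kept but flagged (`site_disagreement`); `"require"` and `"ignore"` are available. |

### Cleaning rules

Free-text identifier fields are scanned as a token stream, order-insensitive
across the three layouts observed in practice (`CAD123, Q987`;
`123, Call sign Q987`; `Q987/123`):

* a CAD candidate is the first 1–4 digit numeric token with value under
  7000 (ties beyond the first are counted and reported, not guessed);
  leading zeros parse to the numeric identity ("0123" is CAD 123), and
  five-digit strings are never candidates;
* a call-sign candidate is the first letters-then-digits token that is an
  exact member of the fleet registry after canonicalisation (uppercase,
  punctuation stripped); digits inside a call-sign token are never also
  claimed as a CAD;
* the label words "CAD" and "Call sign" are stripped case-insensitively
  before scanning.

Tokens such as "7421" (a 4-digit number at or above 7000) are rejected
uniformly, whether or not a CAD label precedes them. Duplicate rows —
identical on everything but the row id — collapse to their first
occurrence before parsing.

## What the generator emulates — and what it does not

The generator's defaults describe a metropolitan study area: six acute
trusts (Alpha–Foxtrot) managing thirteen EDs, a conveyed fraction of 0.70
(about 30% of incidents end without ED conveyance), CADs assigned
sequentially from 1 per service day and capped at 6999 so that every
genuine CAD satisfies the "under 7000" cleaning rule, and a generated
call-sign registry emitted as an artifact for the cleaning stage.
Corruption processes are per-trust knobs: blank identifiers
(`null_identifier_rate`, which also stands in for walk-outs and
unregistered patients — one knob rather than separate mechanisms), sentinel
misuse ("136" written in the CAD field for Mental Health Act cases, which
then carry a mental-health diagnosis), exact-copy duplicate rows, absent
cells mis-coded "NULL" instead of "XXXX", uniform ±`timestamp_jitter_minutes`
disagreement between the two systems' clocks (the simplest bounded model of
hand-over imprecision), journeys crossing midnight, multi-patient crew
shifts, and an optional wrong-destination rate (default 0). Every
non-duplicate ED row keeps its ground-truth pair even when its identifiers
are blanked — those rows are exactly the false-non-link candidates.

The preset trust profiles reproduce the *kinds* of behaviour seen across
real trusts (which variables each trust can supply, who uses separate
fields vs one free-text box vs CAD only) with plausible round rates; they
are not calibrated estimates of any real trust, and the distribution of the
three free-text layouts is unknown in reality, so equal-ish mixes were
chosen once per profile.

Limits worth keeping in mind: clinical fields are category labels without
clinical realism; free-text errors are limited to the three published
layouts plus missingness and sentinels (no typos inside tokens — the method
uses exact matching, so a typo behaves identically to a missing
identifier); and arrivals are uniform within the day rather than following
a diurnal demand curve. Passing tests on this generator therefore show the
*algorithm* is correct and robust to the modelled corruptions; they do not
certify performance on any particular real extract.

## The intrinsic false-link mechanism

One behaviour deserves emphasis because it is a property of the method, not
of this implementation. When care crosses midnight (or clock jitter pushes
a recorded arrival past it), the ED row looks up (CAD, arrival date) —
and because CADs reset daily, a *different* incident of the next service
day almost surely owns that key at realistic volumes. The pinned lookup
order (exact date first, then date − 1) cannot detect this: the result is a
confident false link. The brevity that makes the CAD quick to transcribe is
exactly what raises its false-link risk.

Consequently the package's "uncorrupted" reference condition — under which
linkage provably recovers 100% of ground-truth pairs with no false links —
zeroes `midnight_crossing_fraction` and `timestamp_jitter_minutes` along
with the null/misuse/duplicate/mis-coding rates. Simulations with
crossing or jitter enabled exhibit a ~1% false-link rate through precisely
this mechanism, which the truth evaluation quantifies.

## Numerical and degenerate-input choices

* **Rounding.** Match rates are rounded half-up to the nearest integer
  percent (half-up, not banker's, so the convention is deterministic); the
  overall missing-identifier share is reported to one decimal. Under this
  convention the published six-trust reference counts reproduce every one
  of their printed rates, which is the check the convention is tested by.
* **Pathway shares** are quoted as percentages of all *available* records
  (not of matched records), matching how such splits are conventionally
  reported. The shipped reference pathway counts are internally
  inconsistent with their matched total *as published*; the package
  preserves and documents the inconsistency rather than resolving it.
* **Division by zero.** A trust with no available records reports an
  undefined rate marker (`NA`), never an error; precision/recall are `NA`
  when their denominators are empty.
* **Ties.** Equidistant call-sign candidates → `ambiguous_candidates`, no
  match. Multiple CAD candidates in one free-text field → first by
  position, counted in the cleaning report. Multiple ED rows may link to
  one ambulance record (duplicate registrations); the tallies count such
  ambulance records rather than blocking them.
* **Empty inputs.** Empty extracts clean to empty outputs with zeroed
  reports; an extract for sites receiving no conveyances is a warning and
  an empty extract, not an error; empty or unreadable files raise an I/O
  error distinct from validation failure.
* **Problem sizes.** The test suite runs the full pipeline at up to
  ~20,000 ED rows (the scale at which binomial tolerances on recall become
  tight), brute-force oracle comparisons at ≤500 rows across 25 random
  configurations, and the analysis workflow at ~30,000 incidents over 90
  days — sizes chosen so the whole suite runs in well under a minute while
  keeping Monte-Carlo tolerances meaningful.

## Transfer-format validation

The extract specification fixes column titles and order, a comma delimiter,
UTF-8, a mandatory header, the literal "XXXX" for an absent datum, and a
datetime dialect carried explicitly in the spec (ISO-8601 by default, with
a `dd/mm/yyyy hh:mm` dialect provided because UK extracts commonly use it).
Within-field lists use a semicolon sub-delimiter — the one place the
specification had to fix something its source never specified. The
validator reports every violation with rule and locus (wrong missing
marker per cell, renamed titles, re-ordered columns, wrong delimiter,
unparseable datetimes), is pure (same file, same report), and underpins a
strict/best-effort read: strict reads reject citing the report; best-effort
reads emit one warning per violation.

## What the evaluation supplies

`compute_match_report()` produces the per-trust completeness-and-match-rate
table with a totals row; `analyse_unmatched()` flags identifier values
over-represented among unmatched rows (threshold 20 by default — a surfaced
parameter, since no principled rule exists; the signature case is a
sentinel like "136" appearing dozens of times) alongside 24-hour
time-of-day and 0–4 / 5–17 / 18–64 / 65+ age profiles against the matched
rows; `evaluate_against_truth()` computes the confusion counts
(true/false links, false/true non-links) and precision/recall that
de-identified real studies explicitly cannot, which is what makes the
synthetic route scientifically useful: it bounds the behaviour of the
method under each corruption process separately.
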