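---
title: "Engagement views from intervention log data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engagement views from intervention log data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(engagelog)
```

# The problem

Web-based interventions for mental health deliver structured content —
modules of pages in an author-intended order — alongside interactive
features: journals, mindfulness recordings, in-content exercises, and weekly
reviews written by a human supporter. The platform logs every action as
(user, timestamp, URL). Summative adherence measures (modules completed,
weeks active) flatten the *process* of engagement into a total; two users
with identical totals may have radically different trajectories — one reading
linearly, one returning to a single module many times, one living in the
apps. `engagelog` reconstructs that process as four tabular views and their
figures.

# The model

## Sequence assignment

A curated **key file** maps each event identifier to exactly one of:

* a **content label** `module[.subsection[.page]]`, a dotted triple such as
  `2.1.0`; module 0 is legal (introduction modules are common);
* a **feature category** from the closed set Exercise, Mindfulness, Journal,
  Review, Other, Home. `Supporter` and `Feature` are accepted as aliases for
  Review and Other. Home is the landing page and appears in no view.

An identifier matching no key row is `unmapped`: it is kept in the stream,
counted, and excluded from every view (a strict mode turns it into an
error). Mapping is a total, deterministic function of the identifier.

Matching is *suffix-or-exact* after stripping one leading `/`: an identifier
matches a pattern if it equals it or ends with `/` followed by it, and the
longest matching pattern wins. The component-boundary requirement prevents a
pattern like `...#carousel1` from swallowing `...#carousel11` — real logs
contain anchor-suffixed URLs where distinct anchors are distinct sub-pages.
URL fragments (`#...`) are therefore part of the pattern, not noise. Some
design questions cannot be answered from URLs at all: an app reached from
inside a content page versus standalone may log the same path. The key file,
not a heuristic, decides each entry's meaning; this is curation by design.

## Content ordinals

The intended reading order is derived from the labels themselves:
module-major, a bare module label before its subsections, a bare subsection
before its pages. The rank of a label in this order is its **content
ordinal**, a bijection onto {0, ..., K−1} for the K distinct content labels
in the key. Labels are stored as full triples; a truncation to
`module.subsection` is available for display (`format_content_label(...,
drop_page = TRUE)`), since running prose usually says "2.1" where the log
says `2.1.0`.

## Sessions

A **session** is a maximal run of one user's events in which no consecutive
gap exceeds the inactivity threshold Δ. The default Δ = 60 minutes is
deliberately generous: users re-watch videos and compose long journal
entries, and a tight threshold would shred such activity into fragments.
Two boundary decisions are fixed by the definition's wording: a gap
*strictly greater* than Δ splits (a gap of exactly Δ does not), and sessions
are never clipped at midnight — the calendar does not segment, only
inactivity does. Session time itself is not a quantity in any view, so the
only effect of Δ is the segmentation.

The bundled worked-example excerpt is instructive: its printed session
column assigns one session number to 63 events that contain a gap of nearly
four hours. That is inconsistent with the stated 60-minute rule, which
yields two sessions. The package follows the rule; the bundled fixture
preserves the printed column as transcription, and the fidelity tests check
the label column only.

## Usage days

A user's usage days are calendar-day offsets from *their own* first event
(day 0), not from a cohort-wide enrollment date — raw logs carry no
enrollment field. A session spanning midnight marks both dates. An optional
anchor could replace the first-event origin; the package keeps the
self-anchored definition because it is computable from the log alone.

## The four views

* **Navigation trace** — per user, the ordered sequence of included events
  (content + the five app categories; Home and unmapped excluded), each
  tagged with its session. Consecutive repeats are retained: repetition of
  content is signal. Rendering demarcates sessions by horizontal space and
  alternating color, and draws the five app categories as stripe lanes above
  the content axis; parity coloring (two hues) stays legible for users with
  dozens of sessions, where a per-session palette would not.
* **Stripe matrix** — the user × day grid of any-use indicators, users
  ordered by first-event date. The formal treatment period end (default day
  56, i.e. 8 weeks) is an attribute drawn as a marker line; substantial use
  beyond it is a finding, not an error, so the axis extends to the last
  observed day.
* **Start–finish rows** — per session with at least one content event, the
  first and last content page *by time* (a session that wanders backwards
  finishes on an earlier page than it reached). Rows sort by finishing
  module then finishing ordinal, ties broken by user id and session index so
  output files are reproducible.
* **Next-action matrix** — counts n_ij of consecutive included-event pairs
  i → j *within sessions only*, row-normalized to likelihoods (rows with no
  outgoing transitions are all-zero rather than undefined). Counting across
  session boundaries would conflate returning-after-days with clicking; a
  flag (`across_sessions`) exists for the other analysis. Self-transitions
  sit on the diagonal by default; `collapse_repeats` merges consecutive
  duplicates first — both are legitimate readings of logs that contain
  literal repeats. Apps enter as five category-level indices appended after
  the content ordinals, not as individual app instances. Transitions are
  pooled over users by default; `per_user_average` averages per-user
  probability matrices instead, weighting users equally rather than by
  activity. The rendered heat map has its origin at the lower left, so
  strictly linear use appears as the one-off diagonal.

Two invariants tie the views to the stream and are enforced by tests: the
matrix's total count equals the sum over sessions of (included length − 1),
and every row of probabilities sums to 1 (within 1e−9) or to 0.

# The synthetic cohort generator

`generate_cohort()` emits a raw log, its key, and ground truth for four
archetypes observed in real cohorts: the **linear completer** (content in
strictly increasing ordinal order), the **repeater** (linear progress plus
revisits of earlier blocks), the **app-focused** user (at least 70% feature
events, nonlinear content), and the **burst user** (sessions in 2–4-day
clusters separated by at least a quiet week).

Defaults are chosen once to mirror a typical 8-week guided program: 8
modules numbered 0–7 (0 an introduction, 6–7 review/optional), each with an
intro label plus 3 subsections × 2 pages (K = 56), a 70-day period so
post-program use exists, about 2 sessions per week, 5–20 events per session,
and a 30% app share (75% for the app-focused archetype, which guarantees the
70% floor by construction). Timestamps are emitted at minute resolution,
matching real platform logs.

One generator decision is load-bearing for testing: within-session gaps are
drawn from 0–8 minutes and between-session gaps are at least 90 minutes —
both *bounded away* from the 60-minute threshold. Recovery of the true
session boundaries by the sessionizer is therefore exact, and the recovery
tests can demand 100% agreement rather than a tolerance. Ground-truth usage
days are computed on the generator's own minute clock, independent of the
ingestion path they validate.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: clock skew and timezone changes, identifiers missing
from the key in bulk (only a 2% stray-URL rate), gaps hovering exactly at
the threshold, supporter review schedules correlated with usage, and
attrition patterns. Conclusions about real cohorts still require real logs.

# Numerical and interface choices

* **Timestamps** parse day-first (`DD/MM/YYYY HH:MM`) by default — the
  dialect of the source logs — with ISO-8601 accepted automatically and the
  format overridable. Times are naive local times; no zone conversion.
  Unparseable rows are dropped, collected with their row numbers in an
  attribute, and reported as one warning; a missing column is fatal and
  names the column.
* **Tie-breaking**: equal timestamps keep input order (minute-resolution
  logs have many same-minute rows whose order is meaningful); the sort is
  stable on (timestamp, input row).
* **Delimiters** auto-detect comma vs tab from the header; encoding is
  UTF-8.
* **Spreadsheets**: each view writes one CSV with a fixed schema and
  round-trips through `read_view_table()` without value change, so
  intermediates can be inspected in any spreadsheet tool.
* **Rendering** never recomputes: every quantitative assertion in the test
  suite is made on view data, not pixels. PNG and SVG are written through
  the cairo devices; identical view + spec yields byte-identical SVG, which
  the tests assert. An empty view still renders a valid "no data" figure.

# Problem sizes used in the test suite

The suite exercises the sessionizer against an independent brute-force gap
scan on 1,000 random streams of up to 40 events, and recovery on synthetic
cohorts of 50 users at five seeds (250 users, roughly 100,000 events in
all); the bundled 63-event excerpt drives the end-to-end and fidelity
checks. These sizes make every property check exhaustive at the scale where
failures would be diagnosable by hand.

# Known limitations

* Regex key patterns are not supported; matching is exact/suffix only.
* No statistical modelling sits on top of the transition matrix (no Markov
  fitting, no significance tests) — the views are exploratory by design.
* The interactive affordances of the original visualization concept
  (cursor, zoom, details-on-demand) are out of scope; SVG output preserves
  element structure for downstream tooling.
* Session-duration analytics are deliberately absent: with a generous
  threshold, session time would be overestimated, and no view here uses it.
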