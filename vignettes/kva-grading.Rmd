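---
title: "KVA grading: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{KVA grading: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kvagrade)
```

## The grading problem

Belantamab mafodotin causes dose-modifiable corneal toxicity. Trials
manage it with the Keratopathy Visual Acuity (KVA) scale: per eye, a
grade for the change in best-corrected visual acuity (BCVA) from the
treatment baseline and a grade for corneal-examination findings; the
overall grade — the most severe finding across both components of both
eyes — drives dose delays and reductions. `kvagrade` implements that
computation as a library plus CLI. It deliberately stops at the grade:
it makes no dosing recommendation and persists no patient data.

## The acuity chart and unit independence

All arithmetic happens on a canonical chart in which one row is one line
of vision, spaced uniformly at 0.1 logMAR. The default (`default_chart()`)
spans logMAR −0.3…2.0 (Snellen 20/10…20/2000, 24 rows) with denominators
on the conventional 1 / 1.25 / 1.6 / 2 / 2.5 / 3.2 / 4 / 5 / 6.3 / 8
preferred-number ladder, and decimal acuity listed as the ladder value
nearest $10^{-\mathrm{logMAR}}$. Listing conventional values matters for
round-tripping: the row 20/32 lists decimal 0.63 (what a chart prints and
a user types), not the raw quotient 0.625, and `convert_acuity()` is a
lookup of these listed representations, never recomputed floating point.
Equally, strict parsing matches a reading against the row's *listed*
representation in its own unit: `"20/25"` belongs to the logMAR 0.1 row
even though $\log_{10}(25/20) = 0.0969$. A 1e−9 tolerance absorbs decimal
round-off; it is far below the 0.05-logMAR midpoint between rows, so no
input can be ambiguous. The chart is config-replaceable
(`load_chart()`), so a chart dialect with traditional 20/30-style lines
can be dropped in; validation enforces the 0.1-logMAR spacing,
monotonicity of all three representations, and the presence of the 20/20
and 20/200 anchor rows.

Two entry policies exist because clinical front-ends constrain input to
chart values but scripted pipelines may not: `strict` (default) rejects
off-chart readings, naming the two nearest rows; `nearest` snaps to the
row with minimal absolute logMAR difference, breaking ties toward the
*worse* row — the conservative direction for toxicity monitoring — and
flags the value as snapped in the audit trail. Non-numeric categories
(count fingers, hand motion, light/no light perception) are rejected,
not graded: they are off the scale this package implements.

## The BCVA-change component as precompiled transition models

A grade change is not simply the number of lines declined: any decline
landing at or beyond the 20/200 row is grade 4 regardless of its length.
So the mapping (baseline row, current row) → grade is compiled eagerly:
for each baseline row, a total transition table over all current rows
(`compile_model()`, `compile_library()` — 24 models on the default
chart). `apply_model()` is then a pure lookup; thresholds are never
re-evaluated at query time. This buys three things: the unit-invariance
argument reduces to correctness of a single table (readings in any unit
resolve to the same row before lookup); the whole decision surface can
be exported and audited (`export_library()`, JSON with stable key order,
or Graphviz DOT with the no-change/improvement edges omitted for
readability); and staleness is detectable — each model carries MD5
fingerprints of its chart and scale, and a library import whose
fingerprints do not match its reconstructed configuration is rejected.

The line thresholds sit in `kva_scale()` (defaults: 1 line → grade 1,
2–3 lines → grade 2, more than 3 lines → grade 3, all conditional on the
current reading being better than the 20/200 cutoff; any decline to the
cutoff or beyond → grade 4; decline ≤ 0 → N/A). The constructor rejects
configurations whose ranges would leave some decline ungraded, keeping
every compiled table total. Grade 4 is gated on an actual decline: a
patient whose baseline was already 20/200 or worse and is stable grades
N/A, since a change component with no change has nothing to grade. N/A
is displayed distinctly but ranks as grade 0 when combined, because
stable or improving vision carries no dose-modification weight.

## The corneal component as a gated questionnaire

The corneal exam is a five-question dropdown schema
(`default_schema("dreamm_kva")`): superficial punctate keratopathy
(none/mild/moderate/severe → contributions 0/1/2/3), microcyst-like
epithelial changes (documentation), predominant findings location —
*enabled only when* SPK or MECs report a finding, epithelial defect
(yes → 4), and other clinically significant findings (documentation).
Gating predicates are declarative data (OR-of-AND conditions over
earlier answers), so a schema is a config file, not code: the SPK
wording, the five-question structure and the defect→4 linkage are fixed
by the scale, while the remaining prompts, vocabularies, contributions
and gates are conventional defaults that `load_schema()` can replace
wholesale (including whether location modulates the SPK grade — the
default says it does not). `validate_responses()` enforces the gating
both ways: an unanswered enabled question and an answered disabled one
("location = central" with no findings — an impossible scenario) are
both errors, so `grade_corneal()` only ever sees exactly the valid
combinations. The grade is the maximum contribution over answered
questions — the same most-severe-finding principle as everywhere else.
The `clear_cornea` schema variant prepends a single "clear cornea?"
prompt whose *yes* disables every subsequent question and fixes the
grade at 0.

## Combination and reporting

`compute_overall()` is a pure max over the four component labels with
N/A ≡ 0; per-eye and overall grades are its partial maxima. Reports echo
every raw input string verbatim, flag snapped values, and record the
chart/scale/schema fingerprints; the text layout puts the right eye (OD)
in the left column, matching how clinicians face the patient. JSON
reports are stable-ordered, so identical sessions render byte-identical
reports.

## What the synthetic generator emulates — and what it does not

`generate_sessions()` provides seeded synthetic visits for property
tests and demos. Defaults, chosen once as a plausible monitoring mix:
eyes decline with probability 0.5, mostly by 1–4 lines
(0.35/0.25/0.15/0.10 over 1–4, tapering to 10); SPK severity
0.45/0.30/0.15/0.10 over none→severe; epithelial defects 5%;
microcyst-like changes 20%; the three units equally likely. Baselines
are sampled uniformly among rows that admit the sampled decline, and
corneal answers are sampled question-by-question through the gating
predicates, so every generated session is valid by construction — which
is exactly what the invariance suites need. A `jitter` option perturbs
the logMAR values off-chart to exercise the `nearest` snap policy. The
generator does not emulate real toxicity epidemiology: no correlation
between eyes or between SPK and acuity decline, no longitudinal
trajectories, no measurement noise beyond the optional jitter. Passing
tests therefore certify the *computation* — unit invariance,
lookup-vs-recomputation equivalence, gating soundness — not any clinical
distribution of grades.

## Numerical and testing choices

Everything is exact integer/row arithmetic once parsing is done; the
only tolerances are the 1e−9 representation matches above. Test problem
sizes: the transition surface is checked exhaustively (24 × 24 pairs
against an independently written brute-force grader, in all three
units), the corneal truth table exhaustively over all valid response
combinations, the overall combiner over all 6⁴ label tuples, and unit
invariance over 1,000 generated sessions at a fixed seed; the decline
frequency of the generator is checked over 2,000 sessions against a
3-standard-error band.

## Known limitations

The exact published KVA thresholds and corneal question wordings beyond
the anchors above live in trial documentation; the defaults here honor
every documented anchor, and all of them — chart rows, scale thresholds,
question schema — are configuration, not code, so a corrected source
drops in without a package change. ETDRS letter scores, near vision,
CF/HM/LP/NLP categories and dose-modification advice are out of scope.
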