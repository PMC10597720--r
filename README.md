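# kvagrade

Semi-automated **Keratopathy Visual Acuity (KVA)** grading for belantamab
mafodotin (belamaf) ocular-toxicity monitoring. Belamaf dosing in multiple
myeloma is modified according to an overall KVA grade that combines, per
eye, (a) the change in best-corrected visual acuity (BCVA) from baseline
and (b) corneal-examination findings, and takes the most severe finding
across both components of both eyes. Doing this by hand means converting
acuity units, counting chart lines, and walking a conditional decision
tree — slow and error-prone at the slit lamp. `kvagrade` gives eye-care
professionals, trial programmers and safety reviewers a tested,
scriptable implementation of that computation.

## The model

Acuity readings in any of three units — Snellen `20/D`, logMAR, decimal —
are resolved onto a canonical geometric chart in which one row is one
*line of vision* (0.1 logMAR). For a baseline row *b* and current row *c*
(0 = best vision), the BCVA-change grade is

```
decline d = c − b  (lines)

d ≤ 0                      → N/A   (stable or improved; no actionable finding)
current at/worse than 20/200 → 4
d = 1                      → 1
2 ≤ d ≤ 3                  → 2
d > 3                      → 3
```

Because the grade depends on the current reading as well as the decline,
the mapping is precompiled: for each of the 24 baseline rows a total
finite-state transition model maps every current row to its grade label,
and grading at run time is a pure table lookup, identical whichever unit
the readings were entered in. The corneal component is a validated
five-question dropdown schema (superficial punctate keratopathy
none/mild/moderate/severe → grade 0–3, microcyst-like epithelial changes,
findings location — enabled only when a finding exists, epithelial defect
→ grade 4, other findings); impossible answer combinations are rejected,
and an optional "clear cornea?" variant short-circuits the whole exam to
grade 0. Per eye, KVA = max(BCVA grade, corneal grade) with N/A ranking
as 0; overall KVA = max over both eyes.

## Worked example

```r
library(kvagrade)
lib <- compile_library()          # 24 transition models, default chart + scale
session <- exam_session(
  unit     = "snellen",
  baseline = list(od = "20/20", os = "20/20"),
  current  = list(od = "20/25", os = "20/20"),
  corneal  = list(od = c(spk = "none", mec = "no", defect = "no", other = "no"),
                  os = c(spk = "none", mec = "no", defect = "no", other = "no")))
report <- run_session(session, lib)
cat(render_report(report, "text"))
```

```
KVA grade report — anonymous
unit: snellen | chart: etdrs24 | schema: dreamm_kva | snap: strict

                         OD (right eye)           OS (left eye)
  baseline BCVA          20/20                    20/20
  current BCVA           20/25                    20/20
  BCVA change grade      1                        NA
  corneal exam grade     0                        0
  eye KVA grade          1                        0

Overall KVA grade: 1
```

The right eye declined one line (20/20 → 20/25), BCVA-change grade 1; the
left eye is unchanged (N/A); corneas are clean (grade 0); the overall KVA
grade — the most severe finding — is 1. The same command-line call:

```sh
inst/cli/kva grade --unit snellen \
  --baseline-od 20/20 --current-od 20/25 --baseline-os 20/20 --current-os 20/20 \
  --corneal-od spk=none,mec=no,defect=no,other=no \
  --corneal-os spk=none,mec=no,defect=no,other=no
```

Other subcommands: `export-fsa --format json|dot` (inspect or draw the
transition models), `show-chart`, and `make-fixtures --seed N --n K`
(seeded synthetic sessions). Charts, scale thresholds and question
schemas are all replaceable via YAML/JSON config files (`--chart`,
`--scale`, and `load_schema()`).

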