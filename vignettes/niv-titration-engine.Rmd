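---
title: "The NIV titration engine: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The NIV titration engine: model, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nivflow)
```

`nivflow` turns the clinical pathway for initiating and controlling
long-term non-invasive ventilation (NIV) in stable hypercapnic COPD into
an executable rule engine. This vignette is the package's account of that
pathway: the decision rules and their exact boundary conventions, the
state machines, the tunable parameters, what the virtual-patient
simulator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## The decision rules

**Safety gate.** Every blood gas drawn under ventilation passes three
strict-inequality checks: hypoxemia is SpO₂ < 85 %, acidosis is
pH < 7.35 — either aborts the active process immediately with advice to
call a physician — and alkalosis is pH > 7.55, which stops ventilation
and pauses the process for 30 minutes. After the pause a fresh blood gas
is demanded (the triggering sample is never reused); the alkalosis counts
as resolved at pH ≤ 7.55, boundary *included*, mirroring the asymmetry
between the strict trigger and the non-strict recovery test. If it is
resolved and the patient approves, ventilation restarts with IPAP lowered
by 2 mbar; otherwise the process aborts. When an abort reason co-occurs
with alkalosis on a hand-constructed sample, abort dominates — the
orderings are fixed so the verdict is a function, not a race.

**Nocturnal adequacy and trend.** The morning evaluation classifies the
last on-NIV PaCO₂ of the night. At or below 45 mmHg ventilation is
adequate; above 50 mmHg it needs adjustment outright. Inside the interval
the value counts as an improving trend only when *both* criteria hold:
improved by strictly more than 5 mmHg compared with the patient's lowest
historical value, and strictly lower than the previous measured value.
Three conventions deserve a note:

* The interval's endpoints are not stated in the source pathway; we treat
  it as half-open, (45, 50]: exactly 45 counts as adequate (the
  permissive reading at the favourable boundary), exactly 50 enters trend
  evaluation.
* "More than 5 mmHg" is strict: an improvement of exactly 5.000 mmHg does
  not qualify. `paco2_trend_verdict(49, lowest = 54, previous = 50)`
  returns `NEEDS_ADJUSTMENT`.
* "Improved" means a *lower* PaCO₂ — improvement in hypercapnia is CO₂
  reduction.

The two comparators come from different windows of the record. "Lowest
value of this patient" is the chart lowest from *before the current
night* (history strictly before the night's first on-NIV sample);
"previous measured value" is simply the measurement immediately before
the current one, which during a night is the night's earlier sample. If
both instead derived from one undivided list, the previous measurement
would itself be (or bound) the lowest, and the > 5 mmHg criterion could
never fire for a night that improves on the chart — the rule would be
vacuous. The windowed reading keeps both criteria meaningful and is, we
believe, the clinical intent. `evaluate_paco2_trend()` exposes the
windows as `at` and `history_cutoff`; the pure rule on explicit values is
`paco2_trend_verdict()`.

## The three processes

**INI.** New patients start at the best-practice configuration —
pressure-support mode, IPAP 16, EPAP 5 mbar, backup 18/min, mid-scale
comfort levels — and ventilate for 5 minutes before the questionnaire.
Q1 (air amount) adjusts IPAP by ±2 mbar, capped at 20 mbar during
initiation and floored at EPAP + 2; Q2 (air speed) moves the rise-time
level; Q3 (exhausting to trigger) makes the trigger one level more
sensitive. After any change the patient ventilates again and Q4 is asked
next round; a Q4 "no" reverts to the prior configuration and freezes the
families changed last round. INI ends when a questionnaire round changes
nothing.

**TDT.** Day-time titration ventilates in 20-minute cycles with the blood
gas at minute 15. Within safe values only Q1 is asked; "enough" ends the
process (the pressure is optimal), otherwise IPAP moves ±2 mbar and the
cycle repeats — up to three configuration changes, and only while the
patient approves another cycle. Follow-up control visits load the stored
night configuration; all other entries keep the incoming configuration.

**TNT.** The patient stays overnight: one baseline gas off NIV, two gases
on NIV (4 and 8 hours into the night in the simulator's schedule), the
same safety gates as TDT including the nocturnal stop-pause-retry, then
the morning evaluation. Discharge (option a) requires adequacy *and* full
satisfaction; dissatisfaction resolvable without touching the pressure
(rise time, trigger, an oxygen-flow advisory) repeats the night (option
b); any needed IPAP change — a Q1 complaint or a PaCO₂ needing
adjustment — routes back through TDT and TNT (option c). Transcutaneous
CO₂ estimates enter through the same sample type with a source tag and no
calibration transform.

## The engine

The engine is a pure step function: `advance(session, input)` consumes
exactly one external input — a clock advance in minutes, a blood gas,
questionnaire answers, or an approval — and returns the next session,
never mutating the old one. Time is an abstract monotone minute clock;
nothing sleeps, so every timed rule (the 5-minute pass, the minute-15
gas, the 30-minute pause) is testable instantly. Every transition appends
events (sequence-numbered, clock-stamped) to an append-only log, and the
session records its external inputs, so `replay_session()` reproduces the
final state and log byte-for-byte under the canonical JSON serialisation.

Routing follows the pathway: new patients INI → TDT → TNT; recurring
patients straight to TNT on the stored night configuration (a day-time
control-visit entry is available as an explicit override, since the
source pathway lists it as a TDT entry without routing to it — we
implement both and leave the tension visible rather than resolving it).

Two engine-level safeguards exist that the source pathway does not state,
added because an unbounded outpatient titration is not a clinical
plan: a night whose recommendation is *identical* to the configuration
just slept on (recommendations exhausted, e.g. pressure pinned at a cap)
refers the patient to a physician instead of looping, and a backstop of
`max_tnt_nights = 20` completed nights does the same. Both are ordinary
protocol parameters.

## Tunable parameters

All protocol constants live in `niv_protocol()`. The safety and adequacy
thresholds (85 %, 7.35, 7.55, 45, 50, 5 mmHg) default to the published
values and changing any of them marks the settings — and every batch run
made with them — as nonconforming. Parameters the source pathway leaves
open, with our defaults and reasoning:

| parameter | default | why |
|---|---|---|
| `ipap_step` | 2 mbar | the only pressure delta the pathway states (the post-alkalosis reduction); used symmetrically for all Q1 adjustments |
| `ini_ipap_cap` | 20 mbar | stated for initiation |
| `tdt_ipap_cap` | 30 mbar | the 20-mbar cap is stated *for INI only*; day-time titration aims at an "optimal" pressure, so a device-level ceiling applies |
| `ipap_floor_gap` | 2 mbar | comfort-driven reduction never erases pressure support; no floor is stated |
| `comfort_scale_max` | 5 | rise time and trigger are ordinal levels 1..5 (level 1 = fastest/most sensitive): the pathway names no physical units, and ordinal levels keep the adjustment rules well-defined across devices |
| `ini_family_change_limit` | 3 | total changes per parameter family in INI before it is frozen. A *consecutive same-direction* limit would not terminate (an oscillating too-much/too-little answerer resets it forever); a total cap bounds every run, which the exhaustive state-graph walk in the test suite then proves |
| `max_tnt_nights` | 20 | engine backstop, see above |

## The virtual patient

The simulator exists to exercise every branch of the decision logic, not
to model respiratory mechanics. It is deliberately linear-with-noise:

* PaCO₂ = baseline − sensitivity · (IPAP − EPAP) · (hours on NIV / 8),
  plus Gaussian noise (defaults: baseline 55 mmHg, sensitivity 0.5
  mmHg/mbar, noise SD 1);
* pH = 7.40 + coupling · (PaCO₂ − compensated set point), coupling
  −0.008/mmHg. The set point defaults to the patient's own baseline:
  a *stable* chronic hypercapnic patient is metabolically compensated and
  sits at pH 7.40 despite an elevated PaCO₂. Anchoring pH to a normal
  40 mmHg instead would declare every such patient acidotic at rest and
  abort every simulated course at the first on-NIV gas. Setting
  `compensated_paco2` below baseline models incomplete compensation and
  is how the fuzzing population generates genuinely acidotic courses.
  Overventilation (a large acute CO₂ drop) drives pH up — the
  posthypercapnic alkalosis the stop-pause rule exists for;
* SpO₂ = baseline + 0.3 %/mbar of support while on NIV, clamped.

Answer policies make the patient satisfiable or not: always satisfied,
wants more/less pressure relative to a private IPAP target, or seeded
random. All randomness is drawn from a per-patient stream indexed by a
draw counter, so a (parameters, seed) pair defines one reproducible
response stream, and whole cohorts are reproducible from a single batch
seed.

What the simulator does *not* emulate — and what passing tests therefore
do not show about real patients: cumulative night-to-night CO₂ unloading,
sleep-stage-dependent hypoventilation, mask leak, oxygen-flow physiology,
and any nonlinearity in the pressure–CO₂ relationship. Closed-loop
results (e.g. "a sensitivity-1 patient discharges after one night") are
statements about the decision logic under the linear model, not clinical
predictions.

## Numerical and degenerate-input choices

Pressures are whole mbar (every stated value and delta is integral);
non-integer pressures are rejected rather than rounded. PaCO₂ is fixed to
mmHg. pH outside 6.5–8.0, SpO₂ outside (0, 100] and non-positive PaCO₂
are input errors, not verdicts. The session clock never moves backward;
blood gases older than the newest history entry are rejected, equal
timestamps are allowed (two night samples may share a minute in scripted
tests). A trend evaluation inside (45, 50] with no prior history is a
configuration error directing the caller to record a baseline first. The
problem sizes used by the test suite — an exhaustive walk of the full INI
answer-sequence state graph (about 2 800 distinct states), an exhaustive
TDT answer/approval/gas tree, a 75 000-cell trend-rule grid against a
brute-force oracle, and 1 000 fuzzed closed-loop patients — were chosen
to exhaust the finite alphabets involved while keeping a full run in
minutes.

## Known limitations

The engine models one patient per session and no calendar time; oxygen
flow is advisory text, never a numeric control variable; the nocturnal
"adequate oxygenation" for discharge is the SpO₂ ≥ 85 % safety floor, as
no stricter nocturnal target is stated; and the mapping of
needs-adjustment cases to pressure (option c) versus non-pressure (option
b) changes follows our convention — Q1-driven or PaCO₂-driven implies
pressure — where the source pathway is under-specified.
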