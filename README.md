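# nivflow

Long-term non-invasive ventilation (NIV) is the standard treatment for
chronic hypercapnic respiratory failure in stable COPD, but initiating it
and titrating the ventilator is resource-intensive and usually confined to
specialised centres. `nivflow` implements that clinical pathway as an
executable, auditable rule engine: three interlocking processes —

* **INI** (first initiation): start at a best-practice configuration
  (pressure-support mode, IPAP 16 mbar, EPAP 5 mbar, backup 18/min),
  ventilate 5 minutes, then optimise inspiratory pressure, rise time and
  trigger sensitivity from a 4-item comfort questionnaire, with IPAP capped
  at 20 mbar during initiation;
* **TDT** (day-time titration): 20-minute ventilation cycles with a blood
  gas at minute 15, gated by safety rules — hypoxemia (SpO₂ < 85 %) or
  acidosis (pH < 7.35) aborts with physician referral; alkalosis
  (pH > 7.55) stops ventilation for 30 minutes and restarts at IPAP − 2
  mbar if resolved (pH ≤ 7.55) and the patient approves — and Q1-driven
  pressure steps of ±2 mbar, at most three adjustment cycles;
* **TNT** (night-time titration): one blood gas off NIV before the night
  and two on NIV during it, the same safety gates, then a morning
  evaluation combining the questionnaire with the PaCO₂ criterion: values
  ≤ 45 mmHg are adequate; values in (45, 50] count as an improving trend
  only if improved by **more than 5 mmHg** over the patient's lowest
  historical value *and* lower than the previous measurement. The morning
  routes to discharge (option a), another night (option b), or back
  through day-time titration (option c) whenever the inspiratory pressure
  must change.

A session engine orchestrates the processes (new patients: INI → TDT →
TNT; recurring patients: straight to TNT on the stored night
configuration), owns an abstract minute clock and an append-only audit
log, and is a pure step function over `(session, input)` — so every
session serialises to JSON and replays byte-identically. A seeded
virtual-patient simulator (linear PaCO₂/pH/SpO₂ response with configurable
comfort and approval policies) closes the loop for testing: no clinical
data are required anywhere.

## A worked example

A responsive, satisfied virtual patient whose PaCO₂ falls by 1 mmHg per
mbar of pressure support over a full night:

```r
library(nivflow)

vp  <- virtual_patient("VP1", co2_sensitivity = 1,
                       noise_sd_paco2 = 0, noise_sd_ph = 0)
run <- run_virtual_patient(vp)
run
#> <niv_virtual_run> VP1: DISCHARGED after 1 night(s), final config PS 16/5 mbar, backup 18, rise 3, trigger 3

glance(run$session)
#> # A tibble: 1 × 8
#>   session_id  patient_id status    disposition clock nights n_events final_ipap
#>   <chr>       <chr>      <chr>     <chr>       <dbl>  <int>    <int>      <int>
#> 1 session-VP1 VP1        RECURRING DISCHARGED    500      1       43         16
```

One night at the default pressures (support 16 − 5 = 11 mbar) drives the
nocturnal PaCO₂ from 55 to 44 mmHg — at or below the 45 mmHg adequacy
bound — and the satisfied questionnaire makes the morning evaluation
option a: the patient is discharged after exactly one night, on the
configuration now stored in the record for follow-up. `tidy(run$session)`
returns the full audit log as a tibble; `autoplot(run$session)` plots the
pressure course and the recorded gases.

Sessions persist and replay:

```r
save_session(run$session, "vp1.json")
identical(session_json(replay_session(load_session("vp1.json"))),
          session_json(run$session))
#> [1] TRUE
```

A thin command-line wrapper lives at `inst/cli/nivflow.R`
(`start`, `resume`, `batch`, `replay`, `validate-session`).

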