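---
title: "Evaluating dosing agents against a tacrolimus adjustment protocol"
author: "tacsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating dosing agents against a tacrolimus adjustment protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tacsim)
```

## The problem

Tacrolimus is the first-line calcineurin inhibitor for maintenance
immunosuppression after kidney transplantation. Dosing is steered by
therapeutic drug monitoring: the trough concentration (ng/mL, drawn just
before a dose) is compared with a patient-specific target range, and the
total daily dose (TDD, mg/day, given twice daily) is titrated to keep the
trough in range. Many centers encode this titration as a deterministic
protocol: percentage dose changes stratified by how far the trough lies
from the target range, plus an absolute hold threshold above which one dose
is skipped and the trough rechecked within 24-48 h without touching the
maintenance dose.

`tacsim` provides the infrastructure to *evaluate recommendation sources*
(for example, large language models prompted with such a protocol, or any
other decision-support tool) against the protocol itself: a reference
engine that computes the protocol-exact answer, a generator of stratified
synthetic scenarios, mock agents with controllable error injection, a
hierarchical error grader, and paired evaluation statistics.

## The protocol engine

A protocol is a `tac_protocol`: supported target ranges, adjustment bands,
hold thresholds, a dose increment and an adherence margin.

```{r}
p <- default_protocol()
p
```

For a scenario (trough, TDD, target range) the engine:

1. classifies the trough (`below`, `within`, `above`; membership is
   inclusive at both bounds so boundary troughs are therapeutic);
2. selects the action: `maintain` within range; `hold` at or above the
   hold threshold; otherwise the unique band whose deviation interval
   contains the distance from the violated bound. Deviation intervals are
   lower-exclusive and upper-inclusive, so a deviation of exactly
   1.0 ng/mL takes the 10-20% band — an out-of-range trough always has a
   strictly positive deviation, so nothing is lost at zero;
3. computes the dose range by applying the percentage interval to the TDD;
4. picks the discrete final dose: the feasible 0.5-mg multiple closest to
   the range midpoint (ties toward the lower dose); when the range
   contains no feasible dose, the multiple nearest to the midpoint;
5. splits the final TDD into AM/PM doses differing by at most one
   increment, larger half in the AM slot (a fixed convention — the
   protocol itself never exhibits an uneven split).

```{r}
recommend(5.0, 4.0, target_range(6, 8), p)   # subtherapeutic, +10-20%
recommend(15.4, 6.0, target_range(8, 10), p) # hold override
```

### Configurability and the shipped defaults

The exact institutional band cut-points and hold thresholds are
site-specific and not part of the public protocol description, so they are
*configuration*, not code: `read_protocol()`/`write_protocol()` serialize
protocols as YAML or JSON, and the shipped default
(`system.file("extdata", "default_protocol.yaml", package = "tacsim")`)
encodes deviation <= 1 ng/mL -> 10-20%, 1-2 ng/mL -> 20-30%, > 2 ng/mL ->
30-40% (both directions) with a hold at target-high + 5 ng/mL. These
defaults are consistent with every percentage band the protocol framework
uses and are documented as replaceable. Whether real institutional bands
key on absolute trough rather than relative deviation is unknowable from
the public description; relative deviation was chosen because it applies
uniformly across target ranges.

The 10-12 ng/mL target range is deliberately *unsupported*: it appears in
scenario inputs but has no dosing guidance, and `filter_supported()`
excludes such cases from analysis (the exclusion path of the study
design).

## The synthetic scenario generator

`generate_cases()` reproduces the study design: 100 subtherapeutic, 100
therapeutic and 100 supratherapeutic cases; troughs on a 0.1-ng/mL grid
inside 2.5-15.4 ng/mL; scenarios repeated one to five times to probe
reproducibility; and 12 out-of-protocol cases (target 10-12 ng/mL) so the
exclusion filter retains exactly 288.

Design choices where the study description is silent:

* **Doses.** No dose distribution is published; the current TDD is drawn
  uniformly from a 0.5-mg grid spanning 1.0-12.0 mg/day, which covers the
  3.0-mg case implied by the documented 3.6-3.9-mg dose range.
* **Repetition.** The number of repeated instances among the 288 retained
  cases is reported (211) but not the group-size distribution; the default
  repetition mixture P(1) = 0.56, P(2..5) = 0.11 each gives an expected
  repeated-instance share of 211/288. It is a sampled quantity, so
  individual seeds fluctuate around it.
* **Stratum allocation of excluded cases.** The retained set stratifies as
  90 below / 100 within / 98 above (the figure-consistent counts; the
  running text's 89/100/98 sums to 287). The 12 out-of-protocol cases are
  therefore allocated 10 below / 0 within / 2 above.
* **Path coverage.** The supratherapeutic stratum is guaranteed (when the
  configuration permits) to contain troughs both below and at/above the
  hold threshold, so the decrease and hold paths are both exercised.

What the generator does **not** emulate: longitudinal trough trajectories,
unstructured clinical context, discordant signals, interacting drugs, or
pharmacokinetics linking dose changes to future troughs. Passing tests
therefore demonstrate correctness of the evaluation machinery under the
controlled design, not clinical performance on real patients.

## Agents and the structured output format

Agents return a five-field structured answer (current TDD, percentage
adjustment, dose range, final TDD, AM/PM split; a hold replaces the dose
fields with a hold/recheck marker). `format_output()`/`parse_output()`
round-trip this text form; parsing is tolerant and degrades to a
`parse_status` of `incomplete`, `malformed` or `missing` instead of
raising.

The **oracle agent** serializes the engine's recommendation — it is the
reference answer. The **error-injecting agent** perturbs the oracle answer
per an `error_profile()` of per-error-type probabilities. At most one
sentinel-class perturbation is applied per output (priority hold-omission
> directional > excessive > categorization) so the primary category of a
graded output is predictable; lower-severity perturbations co-occur
freely, matching a taxonomy in which one output contributes to several
granular counts. `phase1_profile()` and `phase2_profile()` are
illustrative presets for a noisier baseline agent and a refined agent;
they characterize the pipeline, and claim nothing about any particular
model. Pre-recorded transcripts (JSONL) can be graded offline through
`transcript_agent()`; no network access is ever involved.

## The grader

`grade_cases()` compares each output with the protocol recommendation for
its case:

* **Adherence**: correct action class, the protocol percentage band, and a
  final TDD inside the protocol dose range or within the +-0.1-mg rounding
  margin of it (a mandated hold is adherent exactly when a hold is
  recommended).
* **Granular errors**: eleven independent detectors (see
  `?detect_errors`). Notable operationalizations:
  * *rounding error* requires direction, percentage and range correct and
    the final dose strictly outside the computed range. It deliberately
    can coexist with adherence via the margin rule — which is how a run
    can show more rounding errors than protocol deviations.
  * *incorrect dose* is the component-level outcome: final dose outside
    range +- margin regardless of cause. *Calculation error* is instead an
    internal-consistency check of the output against its own reported
    percentage, with one increment of slack for rounding. The taxonomy
    names both rows without formal definitions; this reading keeps them
    distinct and reproducible.
  * *excessive dose* uses strict inequalities (beyond doubling, below
    halving, or an implied change exceeding twice the largest protocol
    percentage): at a 1.0-mg TDD the protocol's own best feasible answer
    to a 30-40% reduction is exactly half the dose, which no reasonable
    reading should brand a sentinel error.
  * a hold recommended when none is mandated is graded a holding error
    (sentinel); the omission direction is the clinically observed one, but
    the detector is symmetric.
  * the AM/PM detector checks conservation and the one-increment bound; it
    does not insist the larger half sit in the AM slot, because that
    placement is a serialization convention, not protocol substance.
* **Primary category**: highest severity among the fired errors
  (sentinel > calculation/dosing > administration > formatting), avoiding
  double counting in the primary analysis while granular counts remain
  multi-valued.
* Numerical comparisons use an absolute tolerance of 1e-6 mg on doses and
  1e-9 on percentage fractions, applied before the +-0.1-mg margin.

### Degenerate dose grids

With 0.5-mg increments, narrow percentage ranges on small TDDs can contain
*no* feasible dose (e.g. +20-30% of 3.0 mg/day gives 3.6-3.9 mg). The
grader, following the published error definition, counts any final dose
outside the computed range as a rounding error "despite no feasible
in-range option" — including the reference engine's own choice. Two
consequences are worth stating plainly:

* grading the oracle agent is **not** error-free on case sets containing
  infeasible ranges: it shows rounding errors on exactly those cases (and
  at TDDs below 2 mg/day the nearest feasible dose can even exceed the
  0.1-mg adherence margin, e.g. +10-20% of 1.5 mg/day gives 1.65-1.80 mg
  whose nearest multiples are both 0.15 mg outside);
* this is a property of the discrete dose grid interacting with the
  taxonomy, not an implementation defect, and the test suite pins the
  exact correspondence between infeasible ranges and oracle rounding
  errors.

## Evaluation statistics

Reproducibility is measured on repeated scenarios in two documented ways:
the *mean per-scenario agreement rate* (modal output frequency divided by
repetitions, averaged over scenarios with at least two instances) and the
*instance-level identical fraction* (share of repeated instances matching
their scenario's modal output), the reading that matches statements like
"163 of 211 repeated cases produced identical outputs". Output identity is
exact field equality after parsing, so whitespace can never break
agreement.

Paired adherence between two runs uses McNemar's test on the discordant
cells: exact two-sided binomial for b + c < 25 (the standard small-sample
practice), otherwise the continuity-corrected chi-square
(|b - c| - 1)^2 / (b + c). Report rows whose outcome never occurs in
either arm suppress the test (displayed "-"); concordant-but-present
outcomes report p = 1. Paired t-tests are available for a continuous
deviation metric, defined here (the study never defines or reports one) as
the distance from the final dose to the nearest bound of the protocol
dose range, zero inside it. All displayed percentages are
`round(x, 1)` of a stored count/denominator pair.

## The pipeline

`run_experiment()` wires everything together deterministically from one
seed: generate, filter, run both agents on the identical retained cases,
grade, and report; every artifact (cases, transcripts, grades, report)
carries the seed and a configuration hash. A thin command-line front-end
(`inst/cli/tacsim.R`) exposes `generate`, `recommend`, `simulate-agent`,
`grade`, `evaluate`, `run` and `show-protocol` subcommands over the same
functions.

```{r, message = FALSE}
cfg <- experiment_config(
  generation = generation_config(n_per_stratum = 30, n_out_of_protocol = 4,
                                 out_of_protocol_strata = c(below = 3,
                                                            within = 0,
                                                            above = 1),
                                 seed = 11),
  agent1 = phase1_profile(), agent2 = phase2_profile(),
  labels = c("baseline", "refined"), seed = 11)
report <- run_experiment(cfg)
report
```

## Problem sizes and numerical choices

The default study design (300 cases) runs in a few seconds; the test suite
exercises the full decision grid (every 0.1-ng/mL trough by every 0.5-mg
dose by every supported range) against an independent brute-force
enumeration, and recovers injected error rates on pools of 2,000 cases per
error type — sizes chosen to give the binomial recovery checks useful
power while keeping a full run comfortably interactive. Ties in increment
rounding go up (half-up); ties in midpoint dose selection go to the lower
dose; both are arbitrary but fixed, and the engine is deterministic end to
end.

## Limitations

The framework evaluates *protocol concordance of recommendation sources*,
not clinical benefit. Injected errors are independent across types and
cases, which no real model's error process is; the shipped profiles are
illustrative operating points, not calibrated emulations. Single-protocol
evaluation limits generality across centers, and sequential (longitudinal)
dosing is out of scope by design.
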